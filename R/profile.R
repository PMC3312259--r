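# Per-residue energy profiles: contact environments and total energies.
#
# The environment of residue i is the set of residues j whose C-alpha lies
# within the contact cutoff (default 8 A, boundary inclusive); sequence
# neighbors are not excluded. The total energy is
#   E*_i = sum_{j in Env(i)} (e*_i + e*_j)  =  |Env(i)| e*_i + sum_j e*_j.

# residues x residues logical contact matrix (diagonal FALSE)
.contactMatrix <- function(structure, cutoff) {
  ca <- caCoords(structure)
  d <- as.matrix(stats::dist(ca))
  a <- d <= cutoff
  diag(a) <- FALSE
  a
}

#' Contact environment of a residue
#'
#' Indices of all residues whose C-alpha lies within `cutoff` Angstrom of
#' residue `i`'s C-alpha (boundary inclusive), excluding `i` itself.
#' Symmetric: `j %in% contactsOf(s, i)` iff `i %in% contactsOf(s, j)`.
#'
#' @param structure an [EPStructure-class]
#' @param i residue index (1-based)
#' @param cutoff contact cutoff in Angstrom (default 8)
#' @return integer vector of residue indices
#' @export
contactsOf <- function(structure, i, cutoff = 8) {
  stopifnot(cutoff > 0)
  ca <- caCoords(structure)
  stopifnot(i >= 1L, i <= nrow(ca))
  d <- sqrt(colSums((t(ca) - ca[i, ])^2))
  out <- which(d <= cutoff)
  out[out != i]
}

#' Total pseudoenergy of one residue
#'
#' E*_i = sum over contacts j of (e*_i + e*_j); zero for a residue without
#' contacts.
#'
#' @inheritParams contactsOf
#' @param table a [PseudoEnergyTable-class]
#' @return numeric(1) energy in a.u.
#' @export
residueEnergy <- function(structure, i, table, cutoff = 8) {
  df <- residueTable(structure)
  js <- contactsOf(structure, i, cutoff = cutoff)
  if (length(js) == 0L) return(0)
  ei <- energyFor(table, df$aa[i])
  ej <- energyFor(table, df$aa[js])
  sum(ei + ej)
}

#' Compute the energy profile of a structure
#'
#' Transforms a structure into its one-dimensional energy representation:
#' the ordered vector of total residue energies E*_i. Entries follow
#' residue order. Provenance (pseudoenergy table label, contact cutoff) is
#' recorded in the profile.
#'
#' @param structure an [EPStructure-class]
#' @param table a [PseudoEnergyTable-class]
#' @param cutoff contact cutoff in Angstrom (default 8)
#' @param id profile identifier (default: structure id)
#' @return an [EnergyProfile-class]
#' @export
#' @examples
#' s <- makeHelix(30, seed = 1)
#' computeProfile(s, defaultEnergyTable())
computeProfile <- function(structure, table, cutoff = 8, id = NULL) {
  df <- residueTable(structure)
  if (is.null(id)) id <- structureId(structure)
  e <- energyFor(table, df$aa)
  a <- .contactMatrix(structure, cutoff)
  deg <- rowSums(a)
  energy <- deg * e + as.numeric(a %*% e)
  entries <- data.frame(chain = df$chain, resno = df$resno,
                        aa = df$aa, energy = energy,
                        stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  methods::new("EnergyProfile", id = as.character(id),
               entries = entries,
               statsProvenance = as.character(table@provenance$source_set),
               contactRadius = cutoff)
}

#' Write an energy profile to its text format
#'
#' Header lines `# id`, `# stats`, `# cutoff`, `# version`, then one row per
#' residue: `chain seq_index aa energy` (tab-separated, energies with 10
#' significant digits).
#'
#' @param profile an [EnergyProfile-class]
#' @param file output path
#' @return `file`, invisibly
#' @export
writeProfile <- function(profile, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# id\t%s", profile@id),
               sprintf("# stats\t%s", profile@statsProvenance),
               sprintf("# cutoff\t%s", format(profile@contactRadius)),
               sprintf("# version\t%s", .epVersion())), con)
  df <- profileEntries(profile)
  writeLines(sprintf("%s\t%d\t%s\t%.10g", df$chain, df$resno, df$aa,
                     df$energy), con)
  invisible(file)
}

#' Read an energy profile from its text format
#'
#' @param file path to a file written by [writeProfile()]; trailing
#'   whitespace is tolerated, malformed lines raise an error naming the line
#' @return an [EnergyProfile-class]
#' @export
readProfile <- function(file) {
  if (!file.exists(file)) stop("no such profile file: ", file)
  lines <- readLines(file)
  isMeta <- startsWith(lines, "#")
  meta <- lines[isMeta]
  getMeta <- function(key, default = NA_character_) {
    hit <- grep(paste0("^#\\s*", key, "\\t"), meta, value = TRUE)
    if (length(hit) == 0L) return(default)
    trimws(sub(paste0("^#\\s*", key, "\\t"), "", hit[1]))
  }
  bodyIdx <- which(!isMeta & nzchar(trimws(lines)))
  if (length(bodyIdx) == 0L) stop("malformed profile file: no entries")
  rows <- lapply(bodyIdx, function(ln) {
    fields <- strsplit(trimws(lines[ln]), "\t")[[1]]
    if (length(fields) != 4L)
      stop("malformed profile line ", ln, ": expected 4 tab-separated fields")
    energy <- suppressWarnings(as.numeric(fields[4]))
    resno <- suppressWarnings(as.integer(fields[2]))
    if (is.na(energy) || is.na(resno))
      stop("malformed profile line ", ln, ": non-numeric field")
    data.frame(chain = fields[1], resno = resno, aa = fields[3],
               energy = energy, stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, rows)
  rownames(entries) <- NULL
  methods::new("EnergyProfile",
               id = getMeta("id", "profile"),
               entries = entries,
               statsProvenance = getMeta("stats", "unknown"),
               contactRadius = as.numeric(getMeta("cutoff", "NA")))
}
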