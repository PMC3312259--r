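# Reading and writing the minimal per-residue structure representation.
# Parsing of PDB records is delegated to bio3d; this layer selects models,
# chains, altlocs and atoms, maps residue names, and reconstructs missing
# C-beta positions from backbone geometry.

#' Construct an EPStructure from a residue table
#'
#' Mostly used internally and by the synthetic generators.
#'
#' @param id structure identifier
#' @param residues data.frame with the columns documented in
#'   [EPStructure-class]
#' @return an [EPStructure-class]
#' @export
EPStructure <- function(id, residues) {
  if (is.null(residues$ins)) residues$ins <- ""
  if (is.null(residues$cb_virtual)) residues$cb_virtual <- FALSE
  rownames(residues) <- NULL
  methods::new("EPStructure", id = as.character(id), residues = residues)
}

#' Read a protein structure from a PDB file
#'
#' Retains one residue per canonical amino acid with a C-alpha atom.
#' Selenomethionine (MSE) is mapped to methionine; all other HETATM records
#' and non-canonical residues are dropped (with a warning for the latter).
#' For the first occurring altloc of each atom is kept. If a residue lacks a
#' C-beta atom (glycine, incomplete side chains) but has N, CA and C, an
#' ideal C-beta is reconstructed with [virtualCbeta()].
#'
#' @param file path to a PDB file
#' @param modelIndex 1-based model to read (default first model)
#' @param chains optional character vector restricting to these chain ids
#' @param id structure identifier (default: file base name)
#' @param virtualCb reconstruct missing C-beta atoms from backbone geometry
#'   (default TRUE); when FALSE (or when backbone atoms are missing) the
#'   C-beta stays absent and buriedness classification falls back to the
#'   distance criterion alone
#' @return an [EPStructure-class]
#' @export
#' @examples
#' pdb <- system.file("extdata", "ala_ideal.pdb", package = "eprofiler")
#' readStructure(pdb)
readStructure <- function(file, modelIndex = 1L, chains = NULL, id = NULL,
                          virtualCb = TRUE) {
  if (!file.exists(file)) stop("no such file: ", file)
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(file))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(file, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("unparseable PDB file '", file, "': ",
                             conditionMessage(e))
  )
  nmod <- nrow(pdb$xyz)
  if (modelIndex < 1L || modelIndex > nmod)
    stop("modelIndex ", modelIndex, " out of range (file has ", nmod,
         " model(s))")
  at <- pdb$atom
  xyz <- matrix(pdb$xyz[modelIndex, ], ncol = 3L, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]

  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]

  # ATOM records plus MSE HETATMs; everything else is heteroatom noise here
  keep <- at$type == "ATOM" | (at$type == "HETATM" & at$resid == "MSE")
  at <- at[keep, , drop = FALSE]

  # first occurring altloc per (chain, resno, insert, atom name)
  akey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  at <- at[!duplicated(akey), , drop = FALSE]

  if (nrow(at) == 0L)
    stop("no canonical residues found in '", file, "'")

  rkey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  ukey <- unique(rkey)  # file order preserved

  known <- at$resid %in% names(.AA_THREE2ONE)
  badres <- unique(at$resid[!known])
  if (length(badres) > 0L) {
    warning("dropping non-canonical residue type(s): ",
            paste(badres, collapse = ", "))
  }

  rows <- lapply(ukey, function(k) {
    sub <- at[rkey == k, , drop = FALSE]
    resid <- sub$resid[1]
    if (!resid %in% names(.AA_THREE2ONE)) return(NULL)
    ca <- sub[sub$elety == "CA", , drop = FALSE]
    if (nrow(ca) == 0L) return(NULL)  # no C-alpha: residue excluded
    cb <- sub[sub$elety == "CB", , drop = FALSE]
    cbv <- FALSE
    if (nrow(cb) >= 1L) {
      cbxyz <- c(cb$x[1], cb$y[1], cb$z[1])
    } else if (virtualCb) {
      nat <- sub[sub$elety == "N", , drop = FALSE]
      cat_ <- sub[sub$elety == "C", , drop = FALSE]
      if (nrow(nat) >= 1L && nrow(cat_) >= 1L) {
        cbxyz <- tryCatch(
          virtualCbeta(c(nat$x[1], nat$y[1], nat$z[1]),
                       c(ca$x[1], ca$y[1], ca$z[1]),
                       c(cat_$x[1], cat_$y[1], cat_$z[1])),
          error = function(e) c(NA_real_, NA_real_, NA_real_))
        cbv <- !anyNA(cbxyz)
      } else cbxyz <- c(NA_real_, NA_real_, NA_real_)
    } else cbxyz <- c(NA_real_, NA_real_, NA_real_)
    data.frame(chain = sub$chain[1], resno = sub$resno[1],
               ins = sub$insert[1], aa = unname(.AA_THREE2ONE[resid]),
               ca_x = ca$x[1], ca_y = ca$y[1], ca_z = ca$z[1],
               cb_x = cbxyz[1], cb_y = cbxyz[2], cb_z = cbxyz[3],
               cb_virtual = cbv, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    stop("no canonical residues with a C-alpha atom in '", file, "'")
  EPStructure(id, do.call(rbind, rows))
}

#' Reconstruct an ideal C-beta position from backbone atoms
#'
#' Places a tetrahedral C-beta at 1.53 Angstrom from the C-alpha using the
#' N and C backbone positions, with L-amino-acid chirality. Deterministic;
#' equivariant under rigid-body transformations of the inputs.
#'
#' @param n,ca,c numeric(3) coordinates of the backbone N, CA and C atoms
#' @param bondLength CA-CB bond length in Angstrom (default 1.53)
#' @param angle N-CA-CB angle in degrees (default 110.5)
#' @return numeric(3) C-beta coordinate
#' @export
virtualCbeta <- function(n, ca, c, bondLength = 1.53, angle = 110.5) {
  u1 <- n - ca
  u2 <- c - ca
  if (.vnorm(u1) < 1e-6 || .vnorm(u2) < 1e-6)
    stop("degenerate backbone geometry: coincident atoms")
  u1 <- .unit(u1); u2 <- .unit(u2)
  cr <- .cross3(u1, u2)
  if (.vnorm(cr) < 1e-6)
    stop("degenerate backbone geometry: collinear N, CA, C")
  bis <- .unit(u1 + u2)           # in-plane bisector of N-CA-C
  perp <- .unit(cr)               # plane normal
  # choose the in-plane weight so the N-CA-CB angle hits the target
  alpha <- -cos(angle * pi / 180) / sum(bis * u1)
  if (alpha >= 1) alpha <- 1
  beta <- sqrt(max(0, 1 - alpha^2))
  dirv <- .unit(-bis * alpha + perp * beta)  # + normal: L chirality
  ca + bondLength * dirv
}

#' Write a structure as a minimal PDB file
#'
#' Emits ATOM records for the C-alpha and (where present) C-beta of every
#' residue; intended for fixtures and interchange, not archival deposition.
#'
#' @param structure an [EPStructure-class]
#' @param file output path
#' @return `file`, invisibly
#' @export
writeStructure <- function(structure, file) {
  df <- residueTable(structure)
  n <- nrow(df)
  hasCb <- !is.na(df$cb_x)
  natom <- n + sum(hasCb)
  elety <- character(natom); resno <- integer(natom); resid <- character(natom)
  chain <- character(natom); insert <- character(natom)
  xyz <- numeric(3L * natom)
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    elety[k] <- "CA"; resno[k] <- df$resno[i]
    resid[k] <- unname(.AA_ONE2THREE[df$aa[i]])
    chain[k] <- df$chain[i]; insert[k] <- df$ins[i]
    xyz[(3 * k - 2):(3 * k)] <- c(df$ca_x[i], df$ca_y[i], df$ca_z[i])
    if (hasCb[i]) {
      k <- k + 1L
      elety[k] <- "CB"; resno[k] <- df$resno[i]
      resid[k] <- unname(.AA_ONE2THREE[df$aa[i]])
      chain[k] <- df$chain[i]; insert[k] <- df$ins[i]
      xyz[(3 * k - 2):(3 * k)] <- c(df$cb_x[i], df$cb_y[i], df$cb_z[i])
    }
  }
  insert[insert == ""] <- NA_character_
  bio3d::write.pdb(file = file, xyz = xyz, type = rep("ATOM", natom),
                   resno = resno, resid = resid, eleno = seq_len(natom),
                   elety = elety, chain = chain, insert = insert,
                   end = TRUE)
  invisible(file)
}

#' Split a structure into one structure per chain
#'
#' Energy profiles are computed per chain by default; use the whole
#' structure if cross-chain contacts should contribute.
#'
#' @param structure an [EPStructure-class]
#' @return named list of [EPStructure-class], one per chain, in file order
#' @export
splitChains <- function(structure) {
  df <- residueTable(structure)
  chs <- unique(df$chain)
  out <- lapply(chs, function(ch) {
    EPStructure(paste0(structureId(structure), "_", ch),
                df[df$chain == ch, , drop = FALSE])
  })
  names(out) <- chs
  out
}
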