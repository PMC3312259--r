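# Shared constants and small numeric helpers.

#' Canonical amino acids
#'
#' One-letter codes of the 20 canonical amino acids, in alphabetical order.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aminoAcids()
aminoAcids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# three-letter -> one-letter, MSE (selenomethionine) mapped to M
.AA_THREE2ONE <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
  GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
  MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
  SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y",
  MSE = "M"
)

.AA_ONE2THREE <- c(
  A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
  G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
  M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
  S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR"
)

# Kyte-Doolittle hydropathy, used only by the synthetic buriedness generator
.KYTE_DOOLITTLE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# deterministic 31-bit polynomial string hash, for embedding a config
# fingerprint in outputs (not cryptographic)
.fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.configHash <- function(cfg) {
  .fnv1a(paste(names(cfg), vapply(cfg, function(x) paste(format(x), collapse = ","),
                                  character(1)),
               sep = "=", collapse = ";"))
}

.epVersion <- function() {
  as.character(utils::packageVersion("eprofiler"))
}
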