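## Independent reference constants and brute-force oracles used by the tests.
## These deliberately re-derive masses from the standard residue tables rather
## than calling package internals.

ORACLE_AA <- c(
  G = 57.02146372, A = 71.03711379, S = 87.03202841, P = 97.05276385,
  V = 99.06841392, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295)

ORACLE_GLY <- c(N = 203.07937252, H = 162.05282342, A = 291.09541651,
                F = 146.05790880)
ORACLE_PROTON <- 1.007276466879
ORACLE_WATER <- 18.01056468
ORACLE_NH3 <- 17.02654910

## exhaustive nested-loop enumeration of compositions within tolerance
oracleEnumerate <- function(mass, tol, bounds = c(N = 6, H = 6, A = 4, F = 3)) {
  hits <- character()
  errs <- numeric()
  for (n in 0:bounds["N"]) for (h in 0:bounds["H"])
    for (a in 0:bounds["A"]) for (f in 0:bounds["F"]) {
      m <- n * ORACLE_GLY["N"] + h * ORACLE_GLY["H"] +
        a * ORACLE_GLY["A"] + f * ORACLE_GLY["F"]
      if (abs(m - mass) <= tol) {
        s <- paste0(c("N", "H", "A", "F")[c(n, h, a, f) > 0],
                    c(n, h, a, f)[c(n, h, a, f) > 0], collapse = "")
        hits <- c(hits, s)
        errs <- c(errs, abs(m - mass))
      }
    }
  hits[order(errs, hits)]
}

## naked neutral peptide mass from the reference table (no modifications)
oraclePeptideMass <- function(pep) {
  sum(ORACLE_AA[strsplit(pep, "")[[1]]]) + ORACLE_WATER
}

## a small deterministic random peptide with at least one S/T; Cys is
## excluded so the reference masses need no fixed-modification handling
randomPeptide <- function(len, seed) {
  set.seed(seed)
  res <- sample(setdiff(names(ORACLE_AA), "C"), len, replace = TRUE)
  if (!any(res %in% c("S", "T"))) res[ceiling(len / 2)] <- "T"
  paste(res, collapse = "")
}
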