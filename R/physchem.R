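# Canonical PseAAC physicochemical table: hydrophobicity (h1),
# hydrophilicity (h2) and side-chain mass (m) for the 20 amino acids,
# AAindex-derived values as used throughout the PseAAC literature.
.PHYSCHEM_RAW <- local({
  m <- cbind(
    h1 = c(A =  0.62, C =  0.29, D = -0.90, E = -0.74, F =  1.19,
           G =  0.48, H = -0.40, I =  1.38, K = -1.50, L =  1.06,
           M =  0.64, N = -0.78, P =  0.12, Q = -0.85, R = -2.53,
           S = -0.18, T = -0.05, V =  1.08, W =  0.81, Y =  0.26),
    h2 = c(A = -0.5, C = -1.0, D =  3.0, E =  3.0, F = -2.5,
           G =  0.0, H = -0.5, I = -1.8, K =  3.0, L = -1.8,
           M = -1.3, N =  0.2, P =  0.0, Q =  0.2, R =  3.0,
           S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3),
    m  = c(A =  15, C =  47, D =  59, E =  73, F =  91,
           G =   1, H =  82, I =  57, K =  73, L =  57,
           M =  75, N =  58, P =  42, Q =  72, R = 101,
           S =  31, T =  45, V =  43, W = 130, Y = 107)
  )
  rownames(m) <- names(m[, 1])
  m
})

#' Standardize a physicochemical index over the 20 amino acids
#'
#' Centers and scales one index to zero mean and unit *population* variance
#' across the 20 canonical amino acids (divide by the root mean squared
#' deviation, denominator 20, not 19). This is the standard conversion
#' applied to every index before it enters a correlation function, making
#' hydrophobicity, hydrophilicity and mass commensurable.
#'
#' @param raw Numeric vector of 20 values, one per amino acid in canonical
#'   order (or named by residue letter).
#' @return Numeric vector of 20 standardized values, named by residue.
#' @examples
#' z <- normalize_index(physchem_indices()$raw[, "h1"])
#' mean(z)            # 0
#' mean(z^2)          # 1 (population variance)
#' @export
normalize_index <- function(raw) {
  if (length(raw) != 20L || !is.numeric(raw))
    stop("expected 20 numeric values, one per amino acid", call. = FALSE)
  if (!is.null(names(raw))) raw <- raw[AA_ALPHABET]
  if (anyNA(raw)) stop("index values missing for some amino acids", call. = FALSE)
  mu <- mean(raw)
  sd_pop <- sqrt(mean((raw - mu)^2))
  if (sd_pop == 0)
    stop("degenerate index: all 20 values are equal", call. = FALSE)
  out <- (raw - mu) / sd_pop
  names(out) <- AA_ALPHABET
  out
}

#' Physicochemical index set for correlation-based encoders
#'
#' Returns the three indices (hydrophobicity `h1`, hydrophilicity `h2`,
#' side-chain mass `m`) used by the ACC and SC-PseAAC encoders, both raw
#' and standardized via [normalize_index()]. The shipped values are the
#' canonical AAindex-derived PseAAC table; supply `path` to override them
#' with your own TSV (20 rows: residue letter, h1, h2, m; with header).
#'
#' @param path Optional path to a TSV overriding the packaged values.
#' @return An object of class `physchem_indices`: a list with elements
#'   `names` (index names), `raw` and `normalized` (20 x 3 matrices,
#'   rows in canonical residue order).
#' @export
physchem_indices <- function(path = NULL) {
  if (is.null(path)) {
    raw <- .PHYSCHEM_RAW
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    if (nrow(tab) != 20L || ncol(tab) < 4L)
      stop("index table must have 20 rows and columns: residue, h1, h2, m",
           call. = FALSE)
    raw <- as.matrix(tab[, 2:4])
    rownames(raw) <- toupper(tab[[1]])
    if (!setequal(rownames(raw), AA_ALPHABET))
      stop("index table must cover exactly the 20 canonical amino acids",
           call. = FALSE)
    raw <- raw[AA_ALPHABET, , drop = FALSE]
    colnames(raw) <- c("h1", "h2", "m")
  }
  normalized <- apply(raw, 2, normalize_index)
  rownames(normalized) <- AA_ALPHABET
  structure(list(names = colnames(raw), raw = raw, normalized = normalized),
            class = "physchem_indices")
}
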