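#' The canonical amino-acid alphabet
#'
#' The 20 standard amino acids in the fixed order used for all indexing in
#' this package (profile rows, k-mer enumeration, composition vectors).
#'
#' @format A length-20 character vector: `A C D E F G H I K L M N P Q R S T V W Y`.
#' @export
AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

# sentinel for residues with no usable identity (X and *); windows or residue
# pairs spanning it are excluded from counting
AA_SENTINEL <- "X"

#' Sanitize a protein residue string
#'
#' Uppercases, strips whitespace and alignment gap characters, and maps
#' ambiguity codes onto canonical residues: B→D, Z→E, J→L, U→C, O→K.
#' `X` and `*` become the sentinel residue `X`, which is retained in the
#' string but excluded from k-mer windows and correlation pairs by every
#' encoder (no counted window may span it).
#'
#' @param x Character vector of residue strings.
#' @param id Optional identifier(s) used in error messages.
#' @return Character vector of sanitized residue strings over
#'   `ACDEFGHIKLMNPQRSTVWY` plus the sentinel `X`.
#' @export
sanitize_residues <- function(x, id = NULL) {
  out <- toupper(x)
  out <- gsub("[[:space:].-]", "", out)
  out <- chartr("BZJUO", "DELCK", out)
  out <- gsub("\\*", AA_SENTINEL, out)
  ok <- paste0("^[", paste(AA_ALPHABET, collapse = ""), "]*$")
  bad <- !grepl(ok, out)
  if (any(bad)) {
    who <- if (is.null(id)) which(bad)[1] else id[bad][1]
    ch <- gsub(paste0("[", paste(AA_ALPHABET, collapse = ""), "]"), "",
               out[bad][1])
    stop("record '", who, "': unrecognized residue character(s): ",
         substr(ch, 1, 5), call. = FALSE)
  }
  out
}

# residue string -> integer indices into AA_ALPHABET; sentinel -> NA
aa_ints <- function(residues) {
  idx <- match(strsplit(residues, "", fixed = TRUE)[[1]], AA_ALPHABET)
  idx
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}
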