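#' Read protein sequences from a FASTA file
#'
#' Parses a (multi-record) FASTA file and sanitizes each record with
#' [sanitize_residues()]: residues are uppercased, whitespace and gap
#' characters removed, ambiguity codes substituted (B→D, Z→E, J→L, U→C,
#' O→K, X and * → sentinel `X`). Record order is preserved. The record id
#' is the first whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of residue strings (names are record ids).
#'   An empty file yields an empty vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(structure(character(0), names = character(0)))
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1])
    stop("malformed FASTA in ", path, ": sequence data before first header",
         call. = FALSE)
  rec <- cumsum(is_hdr)
  headers <- trimws(sub("^>", "", lines[is_hdr]))
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids)))
    stop("record ", which(!nzchar(ids))[1], ": empty FASTA header",
         call. = FALSE)
  bodies <- vapply(seq_along(ids), function(r)
    paste(lines[!is_hdr & rec == r], collapse = ""), character(1))
  seqs <- sanitize_residues(bodies, id = ids)
  if (any(!nzchar(seqs)))
    stop("record '", ids[!nzchar(seqs)][1], "': empty sequence",
         call. = FALSE)
  names(seqs) <- ids
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @param width Line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct a frequency profile object
#'
#' A frequency profile is a 20 x L column-stochastic matrix giving, for each
#' sequence position, a probability distribution over the 20 amino acids
#' (rows in canonical order). Columns are renormalized to sum to one.
#'
#' @param matrix Numeric 20 x L matrix of nonnegative frequencies.
#' @param seq_id Identifier of the underlying sequence.
#' @return An object of class `freq_profile`: list with `seq_id` and
#'   `matrix` (rownames `AA_ALPHABET`).
#' @export
freq_profile <- function(matrix, seq_id = "query") {
  if (!is.matrix(matrix) || nrow(matrix) != 20L)
    stop("profile matrix must have 20 rows (amino acids)", call. = FALSE)
  if (any(matrix < 0) || anyNA(matrix))
    stop("profile frequencies must be nonnegative and finite", call. = FALSE)
  cs <- colSums(matrix)
  if (any(cs <= 0))
    stop("profile column ", which(cs <= 0)[1], " sums to zero", call. = FALSE)
  matrix <- sweep(matrix, 2, cs, "/")
  dimnames(matrix) <- list(AA_ALPHABET, NULL)
  structure(list(seq_id = seq_id, matrix = matrix), class = "freq_profile")
}

#' @export
print.freq_profile <- function(x, ...) {
  cat("freq_profile '", x$seq_id, "': 20 x ", ncol(x$matrix),
      " column-stochastic matrix\n", sep = "")
  invisible(x)
}

#' Read a PSI-BLAST ASCII PSSM as a frequency profile
#'
#' Parses the text matrix written by PSI-BLAST's `-out_ascii_pssm` option.
#' Each position row carries the position index, the query residue, 20
#' log-odds integers and 20 weighted observed percentages (plus trailing
#' information-content columns). Only the percentage block is used: it is
#' divided by 100 and each column renormalized to sum to one, approximating
#' the position's target frequency distribution. Positions whose 20
#' percentages are all zero (no alignment information) fall back to a
#' one-hot column at the query residue. The amino-acid column order is taken
#' from the PSSM header line, so any dialect ordering is handled.
#'
#' @param path Path to the ASCII PSSM file.
#' @param seq_id Identifier to attach; defaults to the file name without
#'   extension.
#' @return A [freq_profile()] whose columns each sum to one.
#' @export
read_ascii_pssm <- function(path, seq_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(seq_id)) seq_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  row_re <- "^\\s*[0-9]+\\s+[A-Za-z]\\s+-?[0-9]"
  data_idx <- grep(row_re, lines)
  if (length(data_idx) == 0L)
    stop("no PSSM position rows found in ", path, call. = FALSE)

  # header line with the amino-acid column order: last line before the data
  # that is nothing but single letters (40 for the two blocks, or 20)
  aa_order <- NULL
  for (i in seq_len(data_idx[1] - 1L)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) %in% c(20L, 40L) && all(grepl("^[A-Za-z]$", tok)))
      aa_order <- toupper(tok)
  }
  if (is.null(aa_order))
    aa_order <- rep(c("A","R","N","D","C","Q","E","G","H","I",
                      "L","K","M","F","P","S","T","W","Y","V"), 2L)
  pct_order <- if (length(aa_order) == 40L) aa_order[21:40] else aa_order
  if (!setequal(pct_order, AA_ALPHABET))
    stop("PSSM header does not list the 20 canonical amino acids",
         call. = FALSE)

  mat <- matrix(0, nrow = 20L, ncol = length(data_idx))
  query <- character(length(data_idx))
  for (j in seq_along(data_idx)) {
    ln <- data_idx[j]
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 42L)
      stop("line ", ln, ": expected at least 42 columns in PSSM row, got ",
           length(tok), call. = FALSE)
    pct <- suppressWarnings(as.numeric(tok[23:42]))
    if (anyNA(pct))
      stop("line ", ln, ": non-numeric weighted percentage", call. = FALSE)
    query[j] <- sanitize_residues(tok[2])
    mat[match(pct_order, AA_ALPHABET), j] <- pct / 100
  }
  # uninformative positions: one-hot at the query residue
  zero <- colSums(mat) == 0
  if (any(zero)) {
    qi <- match(query[zero], AA_ALPHABET)
    if (anyNA(qi))
      stop("all-zero PSSM row with non-canonical query residue '",
           query[zero][which(is.na(qi))[1]], "'", call. = FALSE)
    mat[cbind(qi, which(zero))] <- 1
  }
  freq_profile(mat, seq_id = seq_id)
}

#' Collapse a frequency profile to its pseudo-sequence
#'
#' The pseudo-sequence (profile-based protein representation) takes, at each
#' position, the amino acid with maximum frequency in that profile column.
#' Ties are broken deterministically by canonical alphabet order. The
#' resulting string carries the profile's evolutionary information and can
#' be fed to any sequence-based encoder.
#'
#' @param profile A [freq_profile()].
#' @return Length-one named character vector (name = `seq_id`).
#' @export
profile_to_pseudo_sequence <- function(profile) {
  stopifnot(inherits(profile, "freq_profile"))
  idx <- apply(profile$matrix, 2, which.max)  # first max = canonical order
  out <- paste(AA_ALPHABET[idx], collapse = "")
  names(out) <- profile$seq_id
  out
}

#' One-hot frequency profile of a sequence
#'
#' Builds the degenerate profile that puts probability one on the observed
#' residue at every position. Useful as the no-evolutionary-information
#' limit: `profile_to_pseudo_sequence(one_hot_profile(s))` recovers `s`.
#'
#' @param seq Residue string (canonical letters only).
#' @param seq_id Identifier; defaults to the name of `seq` if present.
#' @return A [freq_profile()].
#' @export
one_hot_profile <- function(seq, seq_id = NULL) {
  if (is.null(seq_id)) seq_id <- if (!is.null(names(seq))) names(seq) else "query"
  idx <- aa_ints(unname(seq))
  if (anyNA(idx))
    stop("one-hot profile requires canonical residues only", call. = FALSE)
  m <- matrix(0, nrow = 20L, ncol = length(idx))
  m[cbind(idx, seq_along(idx))] <- 1
  freq_profile(m, seq_id = seq_id)
}

#' Write frequency profiles to TSV
#'
#' Long format: one row per (sequence, position) with columns `seq_id`,
#' `position`, then the 20 canonical amino acids.
#'
#' @param profiles A [freq_profile()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profiles, path) {
  if (inherits(profiles, "freq_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    data.frame(seq_id = p$seq_id, position = seq_len(ncol(p$matrix)),
               t(p$matrix), check.names = FALSE)
  })
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read frequency profiles from TSV written by [write_profile_tsv()]
#'
#' @param path Input path.
#' @return Named list of [freq_profile()] objects.
#' @export
read_profile_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  need <- c("seq_id", "position", AA_ALPHABET)
  if (!all(need %in% colnames(tab)))
    stop("profile TSV must have columns seq_id, position and the 20 amino acids",
         call. = FALSE)
  out <- lapply(split(tab, factor(tab$seq_id, levels = unique(tab$seq_id))),
                function(d) {
                  d <- d[order(d$position), ]
                  freq_profile(t(as.matrix(d[, AA_ALPHABET])),
                               seq_id = d$seq_id[1])
                })
  out[unique(tab$seq_id)]
}
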