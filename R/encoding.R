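#' One-hot (binary) window encoding
#'
#' Encodes a window string as `w` concatenated one-hot blocks of length 21,
#' one per position. Block order is the alphabetical amino-acid order
#' A, C, D, ..., W, Y with the dummy symbol X as the 21st slot, so Ala is
#' `1,0,...,0`. Each block contains exactly one 1.
#'
#' @param window Window string over the 21-letter alphabet.
#' @return Numeric 0/1 vector of length `21 * nchar(window)` with attributes
#'   `scheme = "binary"` and `window_size`.
#' @examples
#' v <- encode_binary_window("A")   # 1 followed by twenty 0s
#' sum(encode_binary_window("AKGYW"))   # one 1 per position
#' @export
encode_binary_window <- function(window) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  idx <- match(chars, ALPHABET21)
  if (anyNA(idx))
    stop_fadpred("fadpred_encoding_error",
                 "illegal character '%s' at window position %d",
                 chars[which(is.na(idx))[1]], which(is.na(idx))[1])
  w <- length(chars)
  v <- numeric(21L * w)
  v[idx + 21L * (seq_len(w) - 1L)] <- 1
  structure(v, scheme = "binary", window_size = w)
}

#' Encode many windows as a binary feature matrix
#'
#' @param windows Character vector of equal-length window strings.
#' @return Numeric matrix, one row per window, `21 * w` columns.
#' @export
encode_binary <- function(windows) {
  w <- unique(nchar(windows))
  if (length(w) != 1L) stop_parameter("windows must share one length")
  m <- matrix(0, nrow = length(windows), ncol = 21L * w)
  chars <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(windows), byrow = TRUE)
  for (p in seq_len(w)) {
    idx <- match(chars[, p], ALPHABET21)
    if (anyNA(idx))
      stop_fadpred("fadpred_encoding_error",
                   "illegal character '%s' in window %d",
                   chars[which(is.na(idx))[1], p], which(is.na(idx))[1])
    m[cbind(seq_len(length(windows)), idx + 21L * (p - 1L))] <- 1
  }
  m
}

#' Normalize a PSI-BLAST log-odds score to \[0, 1\]
#'
#' Default transform is the logistic function `1 / (1 + exp(-val))`:
#' strictly increasing, 0.5 at a raw score of 0, symmetric
#' (`f(v) = 1 - f(-v)`). A dataset min-max alternative is provided via
#' `transform = "minmax"` with the observed `lo`/`hi` bounds. Persisted
#' models record which transform produced their features.
#'
#' @param val Integer raw score(s); vectors and matrices are handled
#'   elementwise.
#' @param transform `"logistic"` (default) or `"minmax"`.
#' @param lo,hi Bounds for the min-max transform (ignored for logistic).
#' @return Values in \[0, 1\], same shape as `val`.
#' @export
normalize_pssm_score <- function(val, transform = c("logistic", "minmax"),
                                 lo = NULL, hi = NULL) {
  transform <- match.arg(transform)
  if (transform == "logistic") return(1 / (1 + exp(-val)))
  if (is.null(lo)) lo <- min(val)
  if (is.null(hi)) hi <- max(val)
  if (hi <= lo) return(val * 0 + 0.5)     # degenerate constant matrix
  pmin(1, pmax(0, (val - lo) / (hi - lo)))
}

#' PSSM-profile window encoding
#'
#' Encodes the window of width `w` centred on `center` as the concatenation
#' of `w` rows of the chain's normalized PSSM (20 values per position).
#' Positions falling outside the chain contribute all-zero rows, so terminal
#' padding is distinguishable from a neutral logistic score of 0.5 and stays
#' uninformative under dot-product kernels.
#'
#' @param chain An [annotated_chain].
#' @param profile The matching [pssm_profile] (same length).
#' @param center 0-based centre index.
#' @param w Odd window size.
#' @return Numeric vector of length `20 * w`, entries in \[0, 1\], with
#'   attributes `scheme = "pssm"` and `window_size`.
#' @export
encode_profile_window <- function(chain, profile, center, w) {
  check_window_size(w)
  L <- length(chain)
  if (nrow(profile$normalized) != L)
    stop_consistency("profile for '%s' has %d rows but chain has %d residues",
                     profile$chain_id, nrow(profile$normalized), L)
  if (center < 0L || center >= L)
    stop_parameter("center %d outside chain of length %d", center, L)
  half <- (w - 1L) %/% 2L
  rows <- (center - half):(center + half)
  m <- matrix(0, nrow = w, ncol = 20L)
  inside <- rows >= 0L & rows < L
  m[inside, ] <- profile$normalized[rows[inside] + 1L, , drop = FALSE]
  structure(as.numeric(t(m)), scheme = "pssm", window_size = w)
}

#' Encode pattern rows as a profile feature matrix
#'
#' @param patterns Data frame with `chain_id` and `center` columns (as from
#'   [extract_windows()]).
#' @param chains Named list of [annotated_chain] (names = chain ids), or an
#'   unnamed list (ids are read from the objects).
#' @param profiles Named list of [pssm_profile] keyed by chain id.
#' @param w Odd window size.
#' @return Numeric matrix, one row per pattern, `20 * w` columns.
#' @export
encode_profiles <- function(patterns, chains, profiles, w) {
  chains <- name_by_id(chains)
  profiles <- name_by_id(profiles)
  m <- matrix(0, nrow = nrow(patterns), ncol = 20L * w)
  for (i in seq_len(nrow(patterns))) {
    id <- patterns$chain_id[i]
    ch <- chains[[id]]; pr <- profiles[[id]]
    if (is.null(ch)) stop_data("no chain with id '%s'", id)
    if (is.null(pr)) stop_data("no PSSM profile for chain '%s'", id)
    m[i, ] <- encode_profile_window(ch, pr, patterns$center[i], w)
  }
  m
}

name_by_id <- function(objs) {
  if (!is.null(names(objs)) && all(nzchar(names(objs)))) return(objs)
  stats::setNames(objs, vapply(objs, function(o) o$chain_id, character(1)))
}

#' Feature encoders for cross-validation
#'
#' Build a closure mapping pattern rows to a feature matrix, for use with
#' [crossvalidate()] and [train_svm()].
#'
#' @param chains,profiles As in [encode_profiles()].
#' @param w Odd window size.
#' @return A function `f(patterns) -> matrix` with attributes `scheme` and
#'   `window_size`.
#' @export
binary_encoder <- function(w) {
  check_window_size(w)
  structure(function(patterns) encode_binary(patterns$window),
            scheme = "binary", window_size = as.integer(w))
}

#' @rdname binary_encoder
#' @export
profile_encoder <- function(chains, profiles, w) {
  check_window_size(w)
  chains <- name_by_id(chains); profiles <- name_by_id(profiles)
  structure(function(patterns) encode_profiles(patterns, chains, profiles, w),
            scheme = "pssm", window_size = as.integer(w))
}

#' Export features in SVM-light sparse or dense TSV form
#'
#' Sparse lines are `label index:value ...` (1-based indices, zeros
#' omitted) — the classic SVM-light dataset dialect.
#'
#' @param x Feature matrix.
#' @param labels 0/1 integer labels (written as +1/-1 in sparse form).
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_svmlight <- function(x, labels, file) {
  stopifnot(nrow(x) == length(labels))
  lines <- vapply(seq_len(nrow(x)), function(i) {
    nz <- which(x[i, ] != 0)
    paste(c(ifelse(labels[i] == 1L, "+1", "-1"),
            sprintf("%d:%g", nz, x[i, nz])), collapse = " ")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_svmlight
#' @export
write_features_tsv <- function(x, labels, file) {
  df <- data.frame(label = labels, x)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
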