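#' Extract overlapping residue windows from a chain
#'
#' Slides an odd-length window over the chain, producing exactly one window
#' per residue. Positions within `(w-1)/2` of either terminus are padded with
#' the dummy symbol X, so terminal residues still get a pattern. Each window
#' is labelled by its centre residue: 1 if the centre is a FAD-interacting
#' residue, else 0.
#'
#' @param chain An [annotated_chain].
#' @param w Odd window size >= 3 (15, 17 and 19 are the standard choices).
#' @param skip_terminal If `TRUE`, windows whose span would extend past a
#'   terminus are dropped instead of padded (no-padding variant).
#' @return A data frame with columns `chain_id`, `center` (0-based index),
#'   `window` (string of length `w`), `label` (0/1 integer).
#' @examples
#' ch <- parse_annotated_fasta(text = c(">c", "aKG"))[[1]]
#' extract_windows(ch, 3)
#' @export
extract_windows <- function(chain, w, skip_terminal = FALSE) {
  stopifnot(inherits(chain, "annotated_chain"))
  check_window_size(w)
  half <- (w - 1L) %/% 2L
  chars <- chain_chars(chain)
  L <- length(chars)
  padded <- c(rep("X", half), chars, rep("X", half))
  centers <- seq_len(L) - 1L
  windows <- vapply(centers, function(c0)
    paste(padded[(c0 + 1L):(c0 + w)], collapse = ""), character(1))
  out <- data.frame(chain_id = chain$chain_id, center = centers,
                    window = windows, label = chain$labels,
                    stringsAsFactors = FALSE)
  if (skip_terminal)
    out <- out[out$center >= half & out$center <= L - 1L - half, , drop = FALSE]
  rownames(out) <- NULL
  out
}

check_window_size <- function(w) {
  if (length(w) != 1L || is.na(w) || w < 3L || w %% 2L == 0L)
    stop_parameter("window size must be a single odd integer >= 3, got %s",
                   paste(w, collapse = ","))
  invisible(as.integer(w))
}

window_size_of <- function(windows) {
  ws <- unique(nchar(windows$window))
  if (length(ws) != 1L)
    stop_parameter("mixed window sizes in pattern set: %s",
                   paste(ws, collapse = ", "))
  as.integer(ws)
}

#' Deduplicate window patterns
#'
#' Keeps one representative per distinct window string per class (first
#' occurrence wins, so output order is deterministic). When the same string
#' occurs with both labels, it is kept once with the label given by
#' `conflict` (default `"positive"`: a missed true interacting residue is
#' the costlier error) and the conflict is counted.
#'
#' @param windows Data frame as returned by [extract_windows()] (rows from
#'   several chains may be concatenated); all rows must share one window size.
#' @param conflict `"positive"` or `"negative"`: class retained for strings
#'   seen with both labels.
#' @param quiet Suppress the conflict message.
#' @return The deduplicated data frame, with attribute `n_conflicts`.
#' @export
deduplicate_patterns <- function(windows, conflict = c("positive", "negative"),
                                 quiet = FALSE) {
  conflict <- match.arg(conflict)
  window_size_of(windows)
  pos <- windows[windows$label == 1L, , drop = FALSE]
  neg <- windows[windows$label == 0L, , drop = FALSE]
  pos <- pos[!duplicated(pos$window), , drop = FALSE]
  neg <- neg[!duplicated(neg$window), , drop = FALSE]
  both <- intersect(pos$window, neg$window)
  if (length(both)) {
    if (!quiet)
      message(sprintf("%d window string(s) occur with both labels; kept as %s",
                      length(both), conflict))
    if (conflict == "positive")
      neg <- neg[!neg$window %in% both, , drop = FALSE]
    else
      pos <- pos[!pos$window %in% both, , drop = FALSE]
  }
  out <- rbind(pos, neg)
  rownames(out) <- NULL
  attr(out, "n_conflicts") <- length(both)
  out
}

#' Build a balanced pattern dataset
#'
#' Draws, uniformly without replacement, as many negative patterns as there
#' are positives. The draw is seeded and happens once per dataset, before
#' any fold assignment.
#'
#' @param positives,negatives Data frames of deduplicated windows of one class
#'   each (columns as in [extract_windows()]).
#' @param seed Integer seed for the negative draw.
#' @return A `pattern_dataset`: list with `window_size`, `patterns` (positives
#'   first, then the sampled negatives), `seed`.
#' @export
sample_balanced_negatives <- function(positives, negatives, seed) {
  if (nrow(negatives) < nrow(positives))
    stop_data("cannot balance: %d positives but only %d negatives",
              nrow(positives), nrow(negatives))
  w <- window_size_of(rbind(positives, negatives))
  idx <- withr::with_seed(seed,
    sample.int(nrow(negatives), nrow(positives), replace = FALSE))
  patterns <- rbind(positives, negatives[idx, , drop = FALSE])
  rownames(patterns) <- NULL
  structure(list(window_size = w, patterns = patterns, seed = as.integer(seed)),
            class = "pattern_dataset")
}

#' @export
print.pattern_dataset <- function(x, ...) {
  cat(sprintf("<pattern_dataset> w=%d: %d positive + %d negative patterns (seed %d)\n",
              x$window_size, sum(x$patterns$label == 1L),
              sum(x$patterns$label == 0L), x$seed))
  invisible(x)
}

#' One-call dataset assembly
#'
#' Convenience pipeline: extract windows from every chain, deduplicate per
#' class, and balance by seeded negative sampling.
#'
#' @param chains List of [annotated_chain] objects.
#' @param w Odd window size.
#' @param seed Seed for the negative draw.
#' @inheritParams deduplicate_patterns
#' @return A `pattern_dataset`.
#' @export
make_pattern_dataset <- function(chains, w, seed, conflict = "positive",
                                 quiet = FALSE) {
  all_w <- do.call(rbind, lapply(chains, extract_windows, w = w))
  dd <- deduplicate_patterns(all_w, conflict = conflict, quiet = quiet)
  sample_balanced_negatives(dd[dd$label == 1L, , drop = FALSE],
                            dd[dd$label == 0L, , drop = FALSE], seed = seed)
}

#' Assign cross-validation folds
#'
#' Random partition of a balanced pattern dataset into `k` folds, stratified
#' by class so each fold holds a nearly equal number of interacting and
#' non-interacting patterns (per-class fold sizes differ by at most 1).
#' With `by_chain = TRUE` whole chains are assigned to folds instead, which
#' prevents near-identical overlapping windows from one chain straddling a
#' train/test split (per-fold class balance is then not guaranteed).
#'
#' @param dataset A `pattern_dataset`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param by_chain Group patterns by source chain instead of splitting at
#'   pattern level.
#' @return Integer vector of fold indices in `1..k`, one per row of
#'   `dataset$patterns`.
#' @export
assign_folds <- function(dataset, k = 5L, seed = 1L, by_chain = FALSE) {
  stopifnot(inherits(dataset, "pattern_dataset"))
  k <- as.integer(k)
  if (k < 2L) stop_parameter("k must be >= 2")
  pat <- dataset$patterns
  n_pos <- sum(pat$label == 1L)
  if (k > n_pos)
    stop_parameter("k = %d exceeds the number of positive patterns (%d)", k, n_pos)
  fold <- integer(nrow(pat))
  if (by_chain) {
    ids <- unique(pat$chain_id)
    ch_fold <- withr::with_seed(seed,
      sample(rep_len(seq_len(k), length(ids))))
    fold <- ch_fold[match(pat$chain_id, ids)]
  } else {
    for (lab in c(0L, 1L)) {
      idx <- which(pat$label == lab)
      fold[idx] <- withr::with_seed(seed + lab,
        sample(rep_len(seq_len(k), length(idx))))
    }
  }
  fold
}

#' Read/write pattern datasets as TSV
#'
#' The on-disk form has columns `chain_id`, `center` (1-based in files,
#' 0-based in memory), `window`, `label`.
#'
#' @param dataset A `pattern_dataset`.
#' @param file Path.
#' @return `write_dataset_tsv` returns `file` invisibly; `read_dataset_tsv`
#'   returns a `pattern_dataset` (its `seed` is taken from the file's
#'   `# seed:` comment when present, else `NA`).
#' @export
write_dataset_tsv <- function(dataset, file) {
  stopifnot(inherits(dataset, "pattern_dataset"))
  pat <- dataset$patterns
  pat$center <- pat$center + 1L
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# fadpred pattern dataset\tw=%d\tseed=%d",
                     dataset$window_size, dataset$seed), con)
  write.table(pat, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_dataset_tsv
#' @export
read_dataset_tsv <- function(file) {
  first <- readLines(file, n = 1L)
  seed <- if (grepl("seed=", first)) as.integer(sub(".*seed=(-?\\d+).*", "\\1", first)) else NA_integer_
  pat <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("chain_id", "center", "window", "label") %in% names(pat)))
    stop_format("dataset TSV must have columns chain_id, center, window, label")
  pat$center <- pat$center - 1L
  structure(list(window_size = window_size_of(pat), patterns = pat, seed = seed),
            class = "pattern_dataset")
}
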