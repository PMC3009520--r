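chain_chars_of <- function(ch) strsplit(ch$residues, "")[[1]]

test_that("window extraction pads termini and labels by centre residue", {
  ch <- parse_annotated_fasta(text = c(">c", "aKG"))[[1]]
  w3 <- extract_windows(ch, 3)
  expect_equal(w3$window, c("XAK", "AKG", "KGX"))
  expect_equal(w3$label, c(1L, 0L, 0L))
  expect_equal(w3$center, 0:2)
})

test_that("extraction emits one window per residue for any chain", {
  withr::with_seed(7, {
    for (i in 1:8) {
      L <- sample(5:120, 1)
      ch <- random_chain("r", L = L)
      for (w in c(15L, 17L, 19L)) {
        ws <- extract_windows(ch, w)
        expect_equal(nrow(ws), L)
        expect_true(all(nchar(ws$window) == w))
        # centre character equals the chain residue at the centre index
        mid <- substr(ws$window, (w + 1) / 2, (w + 1) / 2)
        expect_equal(mid, chain_chars_of(ch))
        expect_equal(sum(ws$label), sum(ch$labels))
      }
    }
  })
})

test_that("even or tiny window sizes are rejected; skip_terminal drops pads", {
  ch <- random_chain(L = 30, seed = 2)
  expect_error(extract_windows(ch, 16), class = "fadpred_parameter_error")
  expect_error(extract_windows(ch, 1), class = "fadpred_parameter_error")
  ws <- extract_windows(ch, 17, skip_terminal = TRUE)
  expect_equal(nrow(ws), 30 - 16)
  expect_false(any(grepl("X", ws$window, fixed = TRUE)))
})

test_that("deduplication keeps one representative per class and is idempotent", {
  ws <- data.frame(chain_id = "c", center = 0:3,
                   window = c("AKG", "AKG", "YWD", "YWD"),
                   label = c(1L, 1L, 0L, 0L))
  dd <- deduplicate_patterns(ws)
  expect_equal(nrow(dd), 2L)
  expect_equal(attr(dd, "n_conflicts"), 0L)
  dd2 <- deduplicate_patterns(dd)
  expect_equal(dd2$window, dd$window)

  distinct <- data.frame(chain_id = "c", center = 0:2,
                         window = c("AAA", "CCC", "DDD"),
                         label = c(1L, 0L, 0L))
  expect_equal(deduplicate_patterns(distinct)$window, distinct$window)
})

test_that("cross-class duplicate strings resolve to positive by default", {
  # two chains constructed so the same window string is once FIR, once not
  ch1 <- parse_annotated_fasta(text = c(">a", "AkG"))[[1]]
  ch2 <- parse_annotated_fasta(text = c(">b", "AKG"))[[1]]
  ws <- rbind(extract_windows(ch1, 3), extract_windows(ch2, 3))
  expect_message(dd <- deduplicate_patterns(ws), "conflict|both labels")
  expect_equal(attr(dd, "n_conflicts"), 1L)
  akg <- dd[dd$window == "AKG", ]
  expect_equal(nrow(akg), 1L)
  expect_equal(akg$label, 1L)
  # configurable: keep as negative instead
  dd_neg <- deduplicate_patterns(ws, conflict = "negative", quiet = TRUE)
  expect_equal(dd_neg[dd_neg$window == "AKG", ]$label, 0L)
  expect_error(deduplicate_patterns(
    data.frame(chain_id = "c", center = 0:1, window = c("AKG", "AKGYW"),
               label = c(1L, 0L))), class = "fadpred_parameter_error")
})

test_that("negative sampling balances classes reproducibly", {
  pos <- data.frame(chain_id = "c", center = 0:9,
                    window = sprintf("A%02d", 0:9), label = 1L)
  neg <- data.frame(chain_id = "c", center = 0:99,
                    window = sprintf("C%02d", 0:99), label = 0L)
  ds <- sample_balanced_negatives(pos, neg, seed = 9)
  expect_equal(sum(ds$patterns$label == 1L), 10L)
  expect_equal(sum(ds$patterns$label == 0L), 10L)
  ds2 <- sample_balanced_negatives(pos, neg, seed = 9)
  expect_identical(ds$patterns, ds2$patterns)
  expect_error(sample_balanced_negatives(neg, pos, seed = 1),
               class = "fadpred_data_error")
})

test_that("negative sampling is uniform across seeds", {
  pos <- data.frame(chain_id = "c", center = 1:10,
                    window = sprintf("A%02d", 1:10), label = 1L)
  neg <- data.frame(chain_id = "c", center = 1:50,
                    window = sprintf("C%02d", 1:50), label = 0L)
  n_rep <- 400
  counts <- integer(50)
  for (s in seq_len(n_rep)) {
    ds <- sample_balanced_negatives(pos, neg, seed = s)
    idx <- match(ds$patterns$window[ds$patterns$label == 0L], neg$window)
    counts[idx] <- counts[idx] + 1L
  }
  p <- 10 / 50
  expected <- n_rep * p
  sigma <- sqrt(n_rep * p * (1 - p))
  expect_true(all(abs(counts - expected) < 3.5 * sigma))
})

test_that("fold assignment partitions with near-equal class balance", {
  mk <- function(n_pos, n_neg) {
    structure(list(window_size = 3L, seed = 1L, patterns = data.frame(
      chain_id = "c", center = seq_len(n_pos + n_neg),
      window = sprintf("W%05d", seq_len(n_pos + n_neg)),
      label = rep(c(1L, 0L), c(n_pos, n_neg)))), class = "pattern_dataset")
  }
  ds <- mk(100, 100)
  f <- assign_folds(ds, 5, seed = 4)
  expect_equal(as.integer(table(f[ds$patterns$label == 1L])), rep(20L, 5))
  expect_equal(as.integer(table(f[ds$patterns$label == 0L])), rep(20L, 5))

  ds2 <- mk(101, 101)
  f2 <- assign_folds(ds2, 5, seed = 4)
  expect_true(all(table(f2[ds2$patterns$label == 1L]) %in% c(20L, 21L)))
  expect_true(all(table(f2[ds2$patterns$label == 0L]) %in% c(20L, 21L)))

  # partition property over random seeds
  for (s in 1:5) {
    fs <- assign_folds(ds2, 5, seed = s)
    expect_length(fs, 202L)
    expect_setequal(unique(fs), 1:5)
  }
  expect_identical(assign_folds(ds, 5, seed = 8), assign_folds(ds, 5, seed = 8))
  expect_error(assign_folds(ds, k = 101, seed = 1),
               class = "fadpred_parameter_error")
})

test_that("chain-grouped folds never split a chain", {
  bench <- small_bench()
  ds <- make_pattern_dataset(bench$chains, 15, seed = 2, quiet = TRUE)
  f <- assign_folds(ds, 5, seed = 2, by_chain = TRUE)
  tab <- table(ds$patterns$chain_id, f)
  expect_true(all(rowSums(tab > 0) == 1L))
})

test_that("dataset TSV round-trips with 1-based file coordinates", {
  bench <- small_bench()
  ds <- make_pattern_dataset(bench$chains, 15, seed = 3, quiet = TRUE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dataset_tsv(ds, f)
  lines <- readLines(f)
  first_row <- strsplit(lines[3], "\t")[[1]]
  expect_equal(as.integer(first_row[2]), ds$patterns$center[1] + 1L)
  back <- read_dataset_tsv(f)
  expect_equal(back$patterns$window, ds$patterns$window)
  expect_equal(back$patterns$center, ds$patterns$center)
  expect_equal(back$window_size, ds$window_size)
  expect_equal(back$seed, ds$seed)
})
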