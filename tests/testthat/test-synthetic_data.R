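test_that("motifs are stamped exactly when mutation is off", {
  spec <- family_spec("w", motifs = list(list(consensus = "WWWWW",
                                              anchor = 0.5)),
                      background = rep(0.05, 20),
                      length_range = c(30L, 40L), mutation_rate = 0)
  recs <- generate_family(spec, 5, seed = 1)
  expect_equal(nrow(recs), 5)
  for (i in 1:5) {
    L <- nchar(recs$residues[i])
    start <- 1 + round(0.5 * (L - 5))
    expect_equal(substr(recs$residues[i], start, start + 4), "WWWWW")
  }
})

test_that("full mutation reverts motif positions to the background rate", {
  spec <- family_spec("m", motifs = list(list(consensus = strrep("W", 10),
                                              anchor = 0.5)),
                      background = rep(0.05, 20),
                      length_range = c(40L, 40L), mutation_rate = 1)
  recs <- generate_family(spec, 200, seed = 2)
  start <- 1 + round(0.5 * (40 - 10))
  motif_chars <- unlist(strsplit(substr(recs$residues, start, start + 9), ""))
  match_rate <- mean(motif_chars == "W")
  expect_lt(abs(match_rate - 1 / 20), 0.05)
})

test_that("generation is deterministic and validates anchors", {
  spec <- family_spec("d", motifs = list(list(consensus = "ACDEF",
                                              anchor = 0.2)),
                      background = rep(0.05, 20))
  r1 <- generate_family(spec, 8, seed = 3)
  r2 <- generate_family(spec, 8, seed = 3)
  expect_identical(r1, r2)

  clash <- family_spec("c", motifs = list(list(consensus = "AAAAA", anchor = 0.5),
                                          list(consensus = "CCCCC", anchor = 0.52)),
                       background = rep(0.05, 20))
  expect_error(generate_family(clash, 1, seed = 1), "overlapping")

  expect_error(family_spec("bad", list(list(consensus = "A", anchor = 0)),
                           background = rep(0.1, 20)), "sum to 1")
  expect_error(family_spec("bad", list(list(consensus = strrep("A", 99),
                                            anchor = 0)),
                           background = rep(0.05, 20)), "longer")
})

test_that("benchmarks have the requested shape and a complete manifest", {
  bench <- generate_benchmark(4, 60, "easy", seed = 1)
  expect_equal(nrow(bench$records), 240)
  expect_equal(length(unique(bench$records$family)), 4)
  expect_equal(unname(table(bench$records$family)), rep(60L, 4),
               ignore_attr = TRUE)
  expect_equal(bench$manifest$separability, "easy")
  expect_length(bench$manifest$specs, 4)
  expect_error(generate_benchmark(1, 10, "easy", 1), "at least 2")
})

signal_gap <- function(records, n_max = 25) {
  # brute-force mean pairwise distances of index-scheme signals, truncated to
  # the shortest length so Euclidean distance is defined
  enc <- encode_records(records, scheme = "index")
  keep <- unlist(lapply(split(seq_len(nrow(enc)), enc$family), head, n_max))
  sigs <- lapply(enc$signal[keep], as.numeric)
  fam <- enc$family[keep]
  L <- min(lengths(sigs))
  m <- do.call(rbind, lapply(sigs, function(s) s[seq_len(L)]))
  d <- as.matrix(dist(m))
  same <- outer(fam, fam, `==`) & upper.tri(d)
  diff_ <- outer(fam, fam, `!=`) & upper.tri(d)
  c(within = mean(d[same]), between = mean(d[diff_]))
}

test_that("easy benchmarks separate families; hard ones shrink the gap", {
  easy <- generate_benchmark(3, 30, "easy", seed = 5)
  hard <- generate_benchmark(3, 30, "hard", seed = 5)
  ge <- signal_gap(easy$records)
  gh <- signal_gap(hard$records)
  expect_gt(ge["between"], ge["within"])
  rel_easy <- (ge["between"] - ge["within"]) / ge["within"]
  rel_hard <- (gh["between"] - gh["within"]) / gh["within"]
  expect_lte(rel_hard, 0.5 * rel_easy)
})
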