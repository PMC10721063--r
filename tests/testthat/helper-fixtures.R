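# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# A small labelled record set written as FASTA + TSV in a temp dir.
fixture_fasta <- function(n_families = 4, n_per_family = 10, seed = 42) {
  key <- paste("fasta", n_families, n_per_family, seed, sep = "_")
  if (is.null(fixture_env[[key]])) {
    bench <- generate_benchmark(n_families, n_per_family, "easy", seed = seed)
    dir <- tempfile("fixture")
    dir.create(dir)
    fasta <- file.path(dir, "seqs.fasta")
    labels <- file.path(dir, "labels.tsv")
    write_fasta(bench$records, fasta, labels_path = labels)
    fixture_env[[key]] <- list(records = bench$records, fasta = fasta,
                               labels = labels, manifest = bench$manifest)
  }
  fixture_env[[key]]
}

# Two-class linearly separable toy images (bright top vs bottom half).
toy_images <- function(n_per_class = 20, size = 16, seed = 1) {
  withr::with_seed(seed, {
    mk <- function(top) {
      a <- array(0, c(size, size, 3))
      rows <- if (top) seq_len(size / 2) else (size / 2 + 1):size
      a[rows, , ] <- 0.9
      a + array(runif(size^2 * 3, 0, 0.05), c(size, size, 3))
    }
    imgs <- c(replicate(n_per_class, mk(TRUE), simplify = FALSE),
              replicate(n_per_class, mk(FALSE), simplify = FALSE))
    list(images = imgs, labels = rep(c("top", "bottom"), each = n_per_class))
  })
}

# Deterministic phase-coupled / phase-randomized cosine triples, built as 64
# independent 128-sample segments (use overlap = 0 to align segments).
coupled_signal <- function(coupled, n_segments = 64, seg = 128, seed = 5,
                           f1 = 0.10, f2 = 0.15) {
  withr::with_seed(seed, {
    unlist(lapply(seq_len(n_segments), function(i) {
      n <- 0:(seg - 1)
      p1 <- 0.3; p2 <- 1.1
      p3 <- if (coupled) p1 + p2 else runif(1, 0, 2 * pi)
      cos(2 * pi * f1 * n + p1) + cos(2 * pi * f2 * n + p2) +
        cos(2 * pi * (f1 + f2) * n + p3)
    }))
  })
}
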