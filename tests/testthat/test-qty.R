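test_that("the QTY mapping is applied exactly inside spans", {
  topo <- tm_topology(data.frame(start = 2, end = 6))
  rec <- qty_transform("MLIVFA", topo)
  expect_equal(rec$variant, "MQTTYA")
  expect_equal(rec$n_substitutions, 4L)
  expect_equal(rec$substitutions[[1]]$position, 2:5)
  expect_equal(rec$substitutions[[1]]$from, c("L", "I", "V", "F"))
  expect_equal(rec$substitutions[[1]]$to, c("Q", "T", "T", "Y"))

  # no span: identity, even for all-substitutable residues
  rec0 <- qty_transform("LLL", tm_topology(data.frame(start = integer(), end = integer())))
  expect_equal(rec0$variant, "LLL")
  expect_equal(rec0$n_substitutions, 0L)

  # span restriction forces exactly one change
  rec1 <- qty_transform("LLL", tm_topology(data.frame(start = 2, end = 2)))
  expect_equal(rec1$variant, "LQL")
  expect_equal(rec1$substitutions[[1]],
               tibble::tibble(position = 2L, from = "L", to = "Q"))
})

test_that("transform is idempotent and local to the spans", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(50:200, 1)
    seq <- random_sequence(n)
    k <- sample(1:4, 1)
    starts <- sort(sample(seq_len(n - 12), k))
    starts <- starts[c(TRUE, diff(starts) > 12)]
    topo <- tm_topology(data.frame(start = starts, end = starts + 8))
    rec <- qty_transform(seq, topo)

    # idempotence: the variant maps to itself
    rec2 <- qty_transform(rec$variant, topo)
    expect_identical(rec2$variant, rec$variant)
    expect_equal(rec2$n_substitutions, 0L)

    # locality: all changes inside spans, everything else untouched
    a <- strsplit(seq, "")[[1]]
    b <- strsplit(rec$variant, "")[[1]]
    mask <- rep(FALSE, n)
    for (j in seq_len(nrow(topo))) mask[topo$start[j]:topo$end[j]] <- TRUE
    expect_true(all(a[!mask] == b[!mask]))
    expect_true(all(which(a != b) %in% which(mask)))
    # changed count equals L/I/V/F count inside spans
    expect_equal(rec$n_substitutions, sum(a[mask] %in% c("L", "I", "V", "F")))
  }
})

test_that("variation percentages match forced counts and brute force", {
  topo <- tm_topology(data.frame(start = 1, end = 4))
  expect_equal(variation_percentages("LLLLAAAA", "QQQQAAAA", topo),
               c(total_pct = 50, tm_pct = 100))
  expect_equal(variation_percentages("AAAA", "AAAA", topo),
               c(total_pct = 0, tm_pct = 0))
  expect_error(variation_percentages("AAA", "AAAA", topo), "length")

  set.seed(99)
  for (i in 1:20) {
    n <- sample(40:120, 1)
    seq <- random_sequence(n)
    s <- sample(seq_len(n - 15), 1)
    topo <- tm_topology(data.frame(start = s, end = s + 10))
    rec <- qty_transform(seq, topo)
    a <- strsplit(seq, "")[[1]]
    b <- strsplit(rec$variant, "")[[1]]
    expect_equal(rec$total_variation_pct, round(100 * sum(a != b) / n, 2))
    expect_equal(rec$tm_variation_pct,
                 round(100 * sum((a != b)[s:(s + 10)]) / 11, 2))
  }
})

test_that("invalid inputs are rejected with clear errors", {
  expect_error(qty_transform("MLXVA", tm_topology(data.frame(start = 1, end = 3))),
               "non-canonical")
  expect_error(qty_transform("MLVA", tm_topology(data.frame(start = 2, end = 9))),
               "exceeds sequence length")
  seqs <- tibble::tibble(id = c("a", "b"), seq = c("LLLL", "VVVV"))
  topo <- tm_topology(data.frame(start = 1, end = 2), sequence_id = "a")
  expect_error(qty_transform(seqs, topo), "no topology entry")
  res <- qty_transform(seqs, topo, allow_missing = TRUE)
  expect_equal(res$variant[res$id == "a"], "QQLL")
  expect_match(res$error[res$id == "b"], "no topology entry")
})

test_that("topology parsing handles both dialects and rejects bad spans", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("FT   TRANSMEM        12..34", "FT   TRANSMEM        50..70"), f)
  topo <- read_topology(f, "uniprot")
  expect_equal(topo$start, c(12L, 50L))
  expect_equal(topo$end, c(34L, 70L))

  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("2\t6", "9\t14"), g)
  expect_equal(read_topology(g, "tsv")$start, c(2L, 9L))

  writeLines(c("2\t6", "5\t9"), g)
  expect_error(read_topology(g, "tsv"), "overlap")
  writeLines(c("6\t2"), g)
  expect_error(read_topology(g, "tsv"), "start > end")
  writeLines(c("a\tb"), g)
  expect_error(read_topology(g, "tsv"), "non-numeric")
})

test_that("alignment rendering marks differences and wraps", {
  topo <- tm_topology(data.frame(start = 1, end = 1))
  rec <- tibble::tibble(native = "LA", variant = "QA")
  txt <- render_alignment(rec, topo)
  lines <- strsplit(unclass(txt), "\n")[[1]]
  expect_equal(lines[3], "*|")

  # identical pair: all bars
  rec2 <- tibble::tibble(native = "AAAA", variant = "AAAA")
  txt2 <- render_alignment(rec2, tm_topology(data.frame(start = integer(), end = integer())))
  expect_equal(strsplit(unclass(txt2), "\n")[[1]][3], "||||")

  # length 70 at width 60: blocks of 60 and 10, sequences recoverable
  seq70 <- random_sequence(70)
  topo70 <- tm_topology(data.frame(start = 11, end = 40))
  rec3 <- qty_transform(seq70, topo70)
  txt3 <- render_alignment(rec3, topo70, width = 60)
  blocks <- strsplit(unclass(txt3), "\n\n")[[1]]
  expect_length(blocks, 2L)
  bl <- lapply(blocks, function(b) strsplit(b, "\n")[[1]])
  expect_equal(nchar(bl[[1]][2]), 60L)
  expect_equal(nchar(bl[[2]][2]), 10L)
  expect_equal(paste0(bl[[1]][2], bl[[2]][2]), seq70)
  expect_equal(paste0(bl[[1]][4], bl[[2]][4]), rec3$variant)
  # helix line marks exactly the span columns
  helix <- paste0(bl[[1]][1], bl[[2]][1])
  expect_equal(which(strsplit(helix, "")[[1]] == "H"), 11:40)

  expect_error(render_alignment(rec, topo, width = 5), "width")
})

test_that("FASTA round-trips through read and write", {
  f <- withr::local_tempfile(fileext = ".fasta")
  tbl <- tibble::tibble(id = c("p1", "p2"),
                        description = c("alpha helix bundle", NA),
                        seq = c(random_sequence(75), random_sequence(40)))
  write_fasta(tbl, f)
  back <- read_fasta(f)
  expect_equal(back$id, tbl$id)
  expect_equal(back$seq, tbl$seq)
  expect_equal(back$description, tbl$description)

  writeLines(c(">bad", "MKXX"), f)
  expect_error(read_fasta(f), "non-canonical")
})
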