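test_that("filter profiles encode the curation presets", {
  p <- filter_profile("nitrilase-blast")
  expect_equal(p$min_identity, 70)
  expect_equal(p$min_coverage, 95)
  expect_equal(p$max_evalue, 1e-10)
  expect_equal(p$length_range, c(200, 500))
  expect_equal(filter_profile("nitrilase-hmm")$length_range, c(50, 500))
  expect_equal(filter_profile("nhase")$length_range, c(200, 300))
  expect_equal(filter_profile("scnase")$length_range, c(175, 300))
  expect_error(filter_profile("bogus"), "unknown preset")
})

test_that("filter_hits boundary semantics", {
  p <- filter_profile("nitrilase-blast")
  hits <- data.frame(
    query = "q", subject = c("h1", "h2", "h3", "h4", "h5"),
    identity = c(69.9, 72, 70, 72, 72),
    coverage = c(96, 95, 95, 95, 95),
    evalue = c(1e-12, 1e-11, 1e-10, 1e-12, 1e-12),
    length = c(300, 300, 300, 500, 501),
    organism = "Some thing", partial = FALSE)
  res <- filter_hits(hits, p)
  # 69.9 identity rejected; inclusive thresholds retain h2 (72/95/1e-11);
  # E-value is strict so 1e-10 is rejected; length 500 in, 501 out
  expect_setequal(res$retained$subject, c("h2", "h4"))
  expect_equal(res$rejections[["identity"]], 1L)
  expect_equal(res$rejections[["evalue"]], 1L)
  expect_equal(res$rejections[["length"]], 1L)
  # empty input
  res0 <- filter_hits(hits[0, ], p)
  expect_equal(nrow(res0$retained), 0)
  expect_true(all(res0$rejections == 0))
})

test_that("rejections count the first failing rule in fixed order", {
  p <- filter_profile("nhase")
  h <- data.frame(query = "q", subject = "h", identity = 10, coverage = 10,
                  evalue = 1, length = 1000, organism = "A b",
                  partial = TRUE)
  res <- filter_hits(h, p)
  expect_equal(res$rejections[["identity"]], 1L)
  expect_true(all(res$rejections[c("coverage", "evalue", "length",
                                   "partial")] == 0))
})

test_that("filter_hits is idempotent and order-invariant", {
  set.seed(20)
  p <- filter_profile("nhase")
  fx <- make_hits_fixture(200, p, margin = 5)
  r1 <- filter_hits(fx$hits, p)
  r2 <- filter_hits(r1$retained, p)
  expect_equal(r1$retained, r2$retained)
  expect_true(all(r2$rejections == 0))
  perm <- fx$hits[sample(nrow(fx$hits)), ]
  r3 <- filter_hits(perm, p)
  expect_setequal(r3$retained$subject, r1$retained$subject)
})

test_that("hit fixtures match planted truth across profiles and seeds", {
  for (preset in c("nitrilase-blast", "nitrilase-hmm", "nhase", "scnase")) {
    p <- filter_profile(preset)
    for (seed in 1:10) {
      fx <- make_hits_fixture(80, p, margin = 4, seed = seed)
      res <- filter_hits(fx$hits, p)
      expect_setequal(res$retained$subject, fx$truth$retained)
      expect_equal(as.integer(res$rejections),
                   as.integer(fx$truth$rejections))
    }
  }
})

test_that("read_hits maps columns and reports malformed lines", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("qseqid\tsseqid\tpident\tqcovs\tevalue\tslen",
               "q1\th1\t75.2\t96\t1e-20\t300",
               "q1\th2\tBAD\t96\t1e-20\t300"), f)
  expect_error(read_hits(f), "line 3")
  writeLines(c("qseqid\tsseqid\tpident\tqcovs\tevalue\tslen",
               "q1\th1\t75.2\t96\t1e-20\t300"), f)
  h <- read_hits(f)
  expect_equal(h$identity, 75.2)
  expect_false(h$partial)
  writeLines(c("qseqid\tsseqid\tpident", "q1\th1\t75.2"), f)
  expect_error(read_hits(f), "lacks required")
})

test_that("subsample_per_genus keeps one longest representative", {
  ids <- c("s1", "s2", "s3")
  orgs <- c("Bacillus pumilus", "Bacillus subtilis", "Neurospora crassa")
  got <- subsample_per_genus(ids, orgs, c(330, 350, 300))
  expect_setequal(got, c("s2", "s3"))
  expect_equal(subsample_per_genus("only", "Genus sp.", 100), "only")
  # ties break lexicographically by id
  got2 <- subsample_per_genus(c("b", "a"), rep("Same genus", 2), c(10, 10))
  expect_equal(got2, "a")
})

test_that("per-genus subsampling matches a group-by oracle", {
  set.seed(21)
  for (rep in 1:10) {
    n <- 100
    genera <- sprintf("G%02d", sample(1:10, n, replace = TRUE))
    orgs <- paste(genera, "sp.")
    ids <- sprintf("id%03d", sample(1:999, n))
    lens <- sample(100:500, n, replace = TRUE)
    got <- subsample_per_genus(ids, orgs, lens)
    expect_length(got, length(unique(genera)))
    want <- vapply(split(seq_len(n), genera), function(i) {
      i[order(-lens[i], ids[i])][1]
    }, 0L)
    expect_setequal(got, ids[want])
  }
})

test_that("catalytic-site check flags gaps at and adjacent to sites", {
  base <- matrix("A", 4, 30,
                 dimnames = list(paste0("s", 1:4), NULL))
  base[, 10] <- "E"; base[, 20] <- "K"; base[, 25] <- "C"
  base["s2", 10] <- "-"          # gap exactly at a site
  base["s3", 21] <- "-"          # gap at site + 1
  base["s4", 22] <- "-"          # gap at site + 2: allowed
  aln <- alignment_matrix(base)
  got <- check_catalytic_sites(aln, c(10, 20, 25), adjacency = 1)
  expect_setequal(got$violators, c("s2", "s3"))
  expect_equal(got$report$n_gap_at[1], 1)
  expect_error(check_catalytic_sites(aln, 31), "out of range")
  # residue mode: mismatched residue at a site is a violation
  base2 <- base
  base2["s1", 25] <- "S"
  got2 <- check_catalytic_sites(alignment_matrix(base2), c(10, 20, 25),
                                expected = c("E", "K", "C"))
  expect_true("s1" %in% got2$violators)
})

test_that("alignment fixtures: planted triad violators found exactly", {
  for (seed in 1:10) {
    fx <- make_alignment_fixture(50, 150, c(20, 60, 100),
                                 n_triad_violators = 5, seed = seed)
    got <- check_catalytic_sites(fx$alignment, c(20, 60, 100))
    expect_setequal(got$violators, fx$truth$triad_violators)
  }
})

test_that("autapomorphic insertions: 20 flags, 19 does not", {
  fx20 <- make_alignment_fixture(30, 200, c(10, 20, 30),
                                 n_insertion_violators = 2,
                                 insertion_len = 20, seed = 3)
  got <- detect_autapomorphic_insertions(fx20$alignment, min_run = 20)
  expect_setequal(got, fx20$truth$insertion_violators)
  fx19 <- make_alignment_fixture(30, 200, c(10, 20, 30),
                                 n_insertion_violators = 2,
                                 insertion_len = 19, seed = 3)
  expect_length(detect_autapomorphic_insertions(fx19$alignment,
                                                min_run = 20), 0)
})

test_that("shared insertions follow the exact other-sequence gap fraction", {
  # n = 40, insertion shared by 2: each sharer sees 38 of its 39 others
  # gapped (0.9744); flagged at 0.95, not at 0.98
  n <- 40; w <- 80
  m <- matrix("A", n, w, dimnames = list(sprintf("q%02d", 1:n), NULL))
  m[, 30:54] <- "-"
  m[1, 30:54] <- "W"; m[2, 30:54] <- "W"
  aln <- alignment_matrix(m)
  frac <- 38 / 39
  got95 <- detect_autapomorphic_insertions(aln, 20, gap_majority = 0.95)
  got98 <- detect_autapomorphic_insertions(aln, 20, gap_majority = 0.98)
  expect_true(frac >= 0.95 && frac < 0.98)
  expect_setequal(got95, c("q01", "q02"))
  expect_length(got98, 0)
})

test_that("trim_columns arithmetic and composition", {
  m <- matrix(sample(c("A", "C", "D"), 40 * 1500, replace = TRUE), 40, 1500)
  rownames(m) <- sprintf("s%02d", 1:40)
  aln <- alignment_matrix(m)
  tr <- trim_columns(aln, 286, 1456)
  expect_equal(ncol(tr), 1171)
  expect_equal(trim_columns(aln, 1, 1500), aln)
  # double trim equals composed single trim
  t2 <- trim_columns(trim_columns(aln, 100, 1200), 50, 600)
  t1 <- trim_columns(aln, 149, 699)
  expect_equal(t2, t1)
  expect_error(trim_columns(aln, 0, 10), "invalid")
  expect_error(trim_columns(aln, 10, 1501), "invalid")
})

test_that("length_summary finds the main mode window", {
  set.seed(22)
  uni <- rnorm(400, 250, 25)
  w <- length_summary(uni)$window
  expect_gt(w[1], 150)
  expect_lt(w[2], 350)
  bi <- c(rnorm(300, 100, 10), rnorm(80, 400, 10))
  wb <- length_summary(bi)$window
  expect_lt(wb[2], 300)            # minority mode excluded
  expect_equal(length_summary(rep(240, 10))$window, c(240, 240))
  expect_error(length_summary(1:3), ">= 5")
})

test_that("alignment FASTA round-trip", {
  fx <- make_alignment_fixture(8, 40, c(5, 15, 25), seed = 1)
  f <- tempfile(fileext = ".fasta")
  write_alignment(fx$alignment, f)
  back <- read_alignment(f)
  expect_equal(unclass(back), unclass(fx$alignment))
})
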