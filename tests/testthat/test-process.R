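make_read <- function(design, sample_row, locus, pattern = NULL) {
  spec <- design$loci[[locus]]
  tpl <- spec$reference_sequence
  for (q in non_cpg_c_positions(spec)) substr(tpl, q, q) <- "T"
  if (!is.null(pattern)) {
    st <- strsplit(pattern, "")[[1]]
    for (k in seq_along(spec$cpg_positions)) {
      substr(tpl, spec$cpg_positions[k], spec$cpg_positions[k]) <- st[k]
    }
  }
  sch <- design$scheme
  x <- sch$forward_codes[[sample_row$x_code]]
  y <- sch$reverse_codes[[sample_row$y_code]]
  rc1 <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  if (spec$forward_end == "X") paste0(x, tpl, rc1(y)) else
    paste0(y, tpl, rc1(x))
}

test_that("demultiplexing assigns, flags chimeras, and rejects unknown codes", {
  d <- demo_design()
  s <- d$scheme$samples
  pca1 <- s[s$group == "PCa", ][1, ]
  hd1 <- s[s$group == "HD", ][1, ]
  r_ok <- make_read(d, pca1, "GSTP1")
  # a PCa X-code paired with an HD Y-code: known codes, unused pair
  cross <- pca1; cross$y_code <- hd1$y_code
  r_chim <- make_read(d, cross, "GSTP1")
  # corrupt the terminal barcode beyond recognition
  r_unk <- r_ok
  substr(r_unk, 1, 8) <- "AAAAAAAA"
  dm <- demultiplex(c(r_ok, r_chim, r_unk), d)
  expect_equal(dm$disposition,
               c("ASSIGNED", "EXCLUDED_CHIMERA", "EXCLUDED_UNASSIGNED"))
  expect_equal(dm$sample_id[1], pca1$sample_id)
  expect_equal(dm$locus[1:2], c("GSTP1", "GSTP1"))
})

test_that("methylation calling reads states and the conversion rate off the reference", {
  d <- demo_design()
  s1 <- d$scheme$samples[1, ]
  spec <- d$loci$GSTP1
  n_cpg <- length(spec$cpg_positions)
  # fully methylated, perfectly converted molecule
  r_meth <- make_read(d, s1, "GSTP1", strrep("C", n_cpg))
  called <- call_methylation(r_meth, spec)
  expect_equal(called$states, strrep("C", n_cpg))
  expect_equal(called$conversion_rate, 1.0)
  # one unconverted non-CpG cytosine: rate = (n_c - 1) / n_c
  ncc <- non_cpg_c_positions(spec)
  r_uncv <- r_meth
  substr(r_uncv, 8 + ncc[1], 8 + ncc[1]) <- "C"
  called <- call_methylation(r_uncv, spec)
  expect_equal(called$conversion_rate,
               (length(ncc) - 1) / length(ncc))
  # a G at a CpG position is an unrecognized site
  r_bad <- r_meth
  substr(r_bad, 8 + spec$cpg_positions[3], 8 + spec$cpg_positions[3]) <- "G"
  called <- call_methylation(r_bad, spec)
  expect_equal(substr(called$states, 3, 3), "N")
})

test_that("a read with exactly 19 of 20 converted cytosines scores 0.95", {
  # definition check on a synthetic 20-cytosine locus
  core <- paste0(paste(rep("CA", 20), collapse = ""), "ACGA")
  ref <- paste0("AAGGAAGGAAGG", core, "TTGGTTGGTTGG")
  spec <- locus_spec("SYN", ref, gregexpr("CG", ref)[[1]][1],
                     "AAGGAAGGAAGG", "CCAACCAACCAA")
  expect_length(non_cpg_c_positions(spec), 20)
  tpl <- ref
  for (q in non_cpg_c_positions(spec)) substr(tpl, q, q) <- "T"
  read <- paste0("TAGATCGC", tpl, "TCGCCTTA")
  substr(read, 8 + non_cpg_c_positions(spec)[1],
         8 + non_cpg_c_positions(spec)[1]) <- "C"
  called <- call_methylation(read, spec)
  expect_equal(called$conversion_rate, 0.95)
})

test_that("retention threshold is inclusive and precedence is deterministic", {
  base <- tibble::tibble(
    sample_id = "S1", group = "HD", locus = "L",
    states = c("CT", "CT", "CN", "CN"),
    conversion_rate = c(0.95, 0.90, 1.0, 0.90),
    disposition = "ASSIGNED")
  tb <- filter_reads(base, min_conversion = 0.95)
  expect_equal(sum(tb$count), 1L)  # only the first read survives
  ex <- exclusion_tallies(tb)
  expect_equal(ex$n[ex$disposition == "EXCLUDED_CONVERSION"], 2L)
  expect_equal(ex$n[ex$disposition == "EXCLUDED_UNRECOGNIZED"], 1L)
})

test_that("dispositions partition all simulated reads (conservation)", {
  d <- demo_design()
  m <- default_calibrated_model(d)   # all noise sources on, 1% chimeras
  sim <- simulate_cohort(m, d, reads_per_sample = 40, seed = 77)
  pt <- process_reads(sim$files, d)
  n_in <- sum(sim$n_reads$n_reads)
  n_out <- sum(pt$count) + sum(exclusion_tallies(pt)$n)
  expect_equal(n_out, n_in)
  expect_true(all(exclusion_tallies(pt)$disposition %in%
                    c("EXCLUDED_UNASSIGNED", "EXCLUDED_CHIMERA",
                      "EXCLUDED_CONVERSION", "EXCLUDED_UNRECOGNIZED")))
})

test_that("noiseless FASTQ processing reproduces the truth table exactly", {
  d <- demo_design()
  sim <- simulate_cohort(noiseless_model(d), d, reads_per_sample = 50,
                         seed = 42)
  pt <- process_reads(sim$files, d)
  got <- dplyr::arrange(tibble::as_tibble(pt), sample_id, locus, pattern)
  want <- dplyr::arrange(sim$truth, sample_id, locus, pattern)
  expect_equal(as.data.frame(got), as.data.frame(want), ignore_attr = TRUE)
})

test_that("processing is idempotent under reverse complement of every read", {
  d <- demo_design()
  sim <- simulate_cohort(noiseless_model(d), d, reads_per_sample = 25,
                         seed = 55, rc_fraction = 0)
  dir2 <- withr::local_tempdir()
  files2 <- character(0)
  for (loc in names(sim$files)) {
    seqs <- Biostrings::readDNAStringSet(sim$files[[loc]], format = "fastq")
    rc <- Biostrings::reverseComplement(seqs)
    p <- file.path(dir2, paste0(loc, ".fastq"))
    lines <- c(rbind(sprintf("@r%d", seq_along(rc)), as.character(rc), "+",
                     strrep("I", Biostrings::width(rc))))
    writeLines(lines, p)
    files2[loc] <- p
  }
  pt1 <- process_reads(sim$files, d)
  pt2 <- process_reads(files2, d)
  expect_equal(
    as.data.frame(dplyr::arrange(tibble::as_tibble(pt1), sample_id, locus,
                                 pattern)),
    as.data.frame(dplyr::arrange(tibble::as_tibble(pt2), sample_id, locus,
                                 pattern)),
    ignore_attr = TRUE)
})

test_that("reads with indels are recovered by the banded fallback aligner", {
  d <- demo_design()
  s1 <- d$scheme$samples[1, ]
  spec <- d$loci$GSTP1
  n_cpg <- length(spec$cpg_positions)
  r <- make_read(d, s1, "GSTP1", strrep("C", n_cpg))
  # delete one base in a primer-distal filler region (not a CpG, not a C)
  fill <- setdiff(seq(40, 100),
                  c(spec$cpg_positions, spec$cpg_positions + 1,
                    non_cpg_c_positions(spec)))
  cut <- 8 + fill[1]
  r_del <- paste0(substr(r, 1, cut - 1), substr(r, cut + 1, nchar(r)))
  dm <- demultiplex(r_del, d)
  expect_equal(dm$disposition, "ASSIGNED")
  called <- call_methylation(r_del, spec)
  expect_true(called$aligned)
  # the deleted position itself may be unrecognized; all CpGs must survive
  expect_equal(called$states, strrep("C", n_cpg))
})

test_that("pair merging follows the overlap and quality tie rules", {
  rc1 <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  set.seed(190)  # aperiodic amplicon so the overlap offset is unambiguous
  amp <- paste(sample(c("A", "C", "G", "T"), 108, replace = TRUE),
               collapse = "")
  # identical fully-overlapping mates reproduce the sequence
  m <- merge_pairs(amp, rc1(amp))
  expect_equal(m$merged, amp)
  # partial overlap: first 80 nt and last 80 nt of the amplicon
  r1 <- substr(amp, 1, 80); r2 <- rc1(substr(amp, 29, 108))
  m <- merge_pairs(r1, r2)
  expect_equal(m$merged, amp)
  # an overlap mismatch with higher quality on read 2 takes read 2's base
  r1_bad <- r1
  wrong <- setdiff(c("A", "C", "G", "T"), substr(amp, 50, 50))[1]
  substr(r1_bad, 50, 50) <- wrong
  q1 <- strrep("#", 80); q2 <- strrep("I", 80)
  m <- merge_pairs(r1_bad, r2, qual1 = q1, qual2 = q2)
  expect_equal(m$merged, amp)
  # equal qualities: the tie goes to read 1
  m <- merge_pairs(r1_bad, r2)
  expect_equal(substr(m$merged, 50, 50), wrong)
  # disjoint mates cannot merge
  m <- merge_pairs(substr(amp, 1, 40), rc1(substr(amp, 61, 108)))
  expect_equal(m$reason, "EXCLUDED_NO_OVERLAP")
})
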