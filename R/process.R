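# Read processing: merged amplicon reads -> per-sample methylation pattern
# tables.  Reads are fixed-structure molecules
#   [8 bp barcode][forward primer][core][rc(reverse primer)][8 bp rc(barcode)]
# so the dominant path is gapless: orient the read, identify the locus by its
# forward primer, exact-match the terminal 8-mers against the barcode lists,
# and read the CpG states straight off the reference coordinates.  Reads
# whose length or mismatch rate rules out the gapless path fall back to a
# banded global alignment against the bisulfite-converted reference with CpG
# and non-CpG-C positions wildcarded.

DISPOSITIONS <- c("RETAINED", "EXCLUDED_UNASSIGNED", "EXCLUDED_CHIMERA",
                  "EXCLUDED_CONVERSION", "EXCLUDED_UNRECOGNIZED")

# per-read mismatch counts of substr(seqs, at..at+len-1) against `ref`
mismatch_count <- function(seqs, ref, at = 1L) {
  n <- nchar(ref)
  mm <- integer(length(seqs))
  for (k in seq_len(n)) {
    mm <- mm + (substr(seqs, at + k - 1L, at + k - 1L) !=
                  substr(ref, k, k))
  }
  mm
}

# locus index per read by forward-primer match at offset 9 (after barcode);
# exact first, then <= max_mm mismatches
assign_locus <- function(seqs, design, max_mm = 2L) {
  out <- rep(NA_integer_, length(seqs))
  loci <- design$loci
  for (li in seq_along(loci)) {
    p <- loci[[li]]$primer_forward
    hit <- is.na(out) & substr(seqs, 9L, 8L + nchar(p)) == p
    out[hit] <- li
  }
  rem <- which(is.na(out))
  if (length(rem) > 0) {
    best_mm <- rep(Inf, length(rem)); best_li <- rep(NA_integer_, length(rem))
    for (li in seq_along(loci)) {
      p <- loci[[li]]$primer_forward
      mm <- mismatch_count(seqs[rem], p, at = 9L)
      better <- mm <= max_mm & mm < best_mm
      best_mm[better] <- mm[better]; best_li[better] <- li
    }
    out[rem] <- best_li
  }
  out
}

#' Demultiplex amplicon reads by dual 8-bp barcodes
#'
#' Orients each read (trying the reverse complement when the forward primer
#' of no locus matches), identifies the locus from the forward primer, and
#' exact-matches the terminal 8-mers against the X/Y code lists in the
#' locus's orientation.  A known-code pair never assigned to a sample is a
#' chimera; a terminal 8-mer matching no code leaves the read unassigned.
#'
#' @param seqs character vector of merged read sequences.
#' @param design an [amplicon_design()].
#' @return tibble with one row per read: `seq` (oriented sequence), `locus`,
#'   `sample_id`, `group`, `disposition` (`ASSIGNED`, `EXCLUDED_CHIMERA` or
#'   `EXCLUDED_UNASSIGNED`).
#' @export
demultiplex <- function(seqs, design) {
  li <- assign_locus(seqs, design)
  flip <- which(is.na(li))
  if (length(flip) > 0) {
    rc_try <- rc_dna(seqs[flip])
    li2 <- assign_locus(rc_try, design)
    ok <- !is.na(li2)
    seqs[flip[ok]] <- rc_try[ok]
    li[flip[ok]] <- li2[ok]
  }
  scheme <- design$scheme
  samples <- scheme$samples
  valid_key <- paste(samples$x_code, samples$y_code)
  out_sample <- rep(NA_character_, length(seqs))
  out_disp <- rep("EXCLUDED_UNASSIGNED", length(seqs))
  loci_names <- names(design$loci)
  for (k in seq_along(design$loci)) {
    idx <- which(li == k)
    if (length(idx) == 0) next
    spec <- design$loci[[k]]
    s8 <- substr(seqs[idx], 1L, 8L)
    len <- nchar(seqs[idx])
    e8 <- rc_dna(substr(seqs[idx], len - 7L, len))
    if (spec$forward_end == "X") {
      f_fam <- scheme$forward_codes; r_fam <- scheme$reverse_codes
    } else {
      f_fam <- scheme$reverse_codes; r_fam <- scheme$forward_codes
    }
    f_lab <- names(f_fam)[match(s8, f_fam)]
    r_lab <- names(r_fam)[match(e8, r_fam)]
    known <- !is.na(f_lab) & !is.na(r_lab)
    x_lab <- if (spec$forward_end == "X") f_lab else r_lab
    y_lab <- if (spec$forward_end == "X") r_lab else f_lab
    m <- match(paste(x_lab, y_lab), valid_key)
    assigned <- known & !is.na(m)
    out_sample[idx[assigned]] <- samples$sample_id[m[assigned]]
    out_disp[idx[assigned]] <- "ASSIGNED"
    out_disp[idx[known & is.na(m)]] <- "EXCLUDED_CHIMERA"
  }
  tibble(
    seq = seqs,
    locus = ifelse(is.na(li), NA_character_, loci_names[li]),
    sample_id = out_sample,
    group = samples$group[match(out_sample, samples$sample_id)],
    disposition = out_disp
  )
}

# banded global alignment (match +1, mismatch -1, gap -2, band `band`)
# against the converted template with CpG and non-CpG-C positions
# wildcarded to {C,T}; returns per-reference-position read characters
# ("-" at deletions) or NULL when identity is below `min_identity`
banded_align <- function(read, spec, band = 10L, min_identity = 0.7) {
  tpl <- strsplit(converted_template(spec), "")[[1]]
  wild <- sort(c(spec$cpg_positions, non_cpg_c_positions(spec)))
  rd <- strsplit(read, "")[[1]]
  n <- length(tpl); m <- length(rd)
  if (abs(m - n) > band) return(NULL)
  NEG <- -1e9
  S <- matrix(NEG, n + 1L, m + 1L)
  S[1, 1] <- 0
  for (j in seq_len(min(m, band))) S[1, j + 1] <- -2 * j
  for (i in seq_len(min(n, band))) S[i + 1, 1] <- -2 * i
  for (i in seq_len(n)) {
    jlo <- max(1L, i - band); jhi <- min(m, i + band)
    for (j in jlo:jhi) {
      hit <- rd[j] == tpl[i] || (i %in% wild && rd[j] %in% c("C", "T"))
      S[i + 1, j + 1] <- max(S[i, j] + (if (hit) 1 else -1),
                             S[i, j + 1] - 2, S[i + 1, j] - 2)
    }
  }
  if (S[n + 1, m + 1] <= NEG / 2) return(NULL)
  # traceback
  out <- character(n)
  i <- n; j <- m; matches <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      hit <- rd[j] == tpl[i] || (i %in% wild && rd[j] %in% c("C", "T"))
      if (S[i + 1, j + 1] == S[i, j] + (if (hit) 1 else -1)) {
        out[i] <- rd[j]; matches <- matches + hit
        i <- i - 1L; j <- j - 1L; next
      }
    }
    if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 2) {
      out[i] <- "-"; i <- i - 1L; next
    }
    j <- j - 1L
  }
  if (matches / n < min_identity) return(NULL)
  out
}

#' Call per-CpG methylation states and the conversion rate
#'
#' Inserts must be primer/barcode-bearing oriented reads with the 8-bp
#' barcodes still attached (as produced by [demultiplex()]); the insert is
#' read at reference offset 9.  At each CpG position C calls METH ("C"),
#' T calls UNMETH ("T"), anything else (or an alignment gap) is
#' unrecognized ("N").  The conversion rate is the fraction of the
#' reference's non-CpG cytosine positions read as T.  Reads whose length or
#' mismatch rate (over non-wildcard positions, > 10%) defeats the gapless
#' path are re-aligned with a banded global alignment; alignment failure
#' marks every state unrecognized and `aligned = FALSE`.
#'
#' @param seqs oriented read sequences (with barcodes).
#' @param spec the [locus_spec()] the reads belong to.
#' @return tibble: `states` (string over C/T/N per CpG), `conversion_rate`,
#'   `aligned` (logical).
#' @export
call_methylation <- function(seqs, spec) {
  n_reads <- length(seqs)
  n_cpg <- length(spec$cpg_positions)
  ncc <- non_cpg_c_positions(spec)
  expected <- 16L + spec$insert_length_bp
  tpl <- converted_template(spec)
  fixed_pos <- setdiff(seq_len(spec$insert_length_bp),
                       c(spec$cpg_positions, ncc))
  states <- rep(strrep("N", n_cpg), n_reads)
  conv <- rep(NA_real_, n_reads)
  aligned <- rep(FALSE, n_reads)

  fast <- which(nchar(seqs) == expected)
  if (length(fast) > 0) {
    ins <- substr(seqs[fast], 9L, 8L + spec$insert_length_bp)
    mm <- mismatch_count_at(ins, tpl, fixed_pos)
    ok <- mm / length(fixed_pos) <= 0.10
    idx <- fast[ok]
    if (length(idx) > 0) {
      ins_ok <- ins[ok]
      cpg_ch <- chars_at(ins_ok, spec$cpg_positions)
      cpg_ch[!(cpg_ch %in% c("C", "T"))] <- "N"
      states[idx] <- do.call(paste0, asplit(cpg_ch, 2))
      cc <- chars_at(ins_ok, ncc)
      conv[idx] <- rowSums(cc == "T") / length(ncc)
      aligned[idx] <- TRUE
    }
    slow_extra <- fast[!ok]
  } else {
    slow_extra <- integer(0)
  }
  slow <- c(setdiff(seq_len(n_reads), fast), slow_extra)
  for (r in slow) {
    al <- banded_align(substr(seqs[r], 9L, nchar(seqs[r]) - 8L), spec)
    if (is.null(al)) next
    st <- al[spec$cpg_positions]
    st[!(st %in% c("C", "T"))] <- "N"
    states[r] <- paste(st, collapse = "")
    conv[r] <- sum(al[ncc] == "T") / length(ncc)
    aligned[r] <- TRUE
  }
  tibble(states = states, conversion_rate = conv, aligned = aligned)
}

# mismatches against template over an explicit position set
mismatch_count_at <- function(seqs, ref, positions) {
  mm <- integer(length(seqs))
  for (p in positions) {
    mm <- mm + (substr(seqs, p, p) != substr(ref, p, p))
  }
  mm
}

#' Apply the retention filters and aggregate a pattern table
#'
#' A read is retained iff its conversion rate is at least `min_conversion`
#' (inclusive) and it has no unrecognized CpG state.  Exclusion precedence
#' is deterministic: unassigned > chimera > conversion > unrecognized, so
#' each read is tallied under exactly one disposition.
#'
#' @param processed tibble with columns `sample_id`, `group`, `locus`,
#'   `states`, `conversion_rate`, `disposition` (from [demultiplex()] /
#'   [call_methylation()]; `ASSIGNED` rows are filtered here).
#' @param min_conversion retention threshold on the conversion rate.
#' @return a [pattern_table()].
#' @export
filter_reads <- function(processed, min_conversion = 0.95) {
  p <- processed
  assigned <- p$disposition == "ASSIGNED"
  unaligned <- assigned & (is.na(p$conversion_rate))
  p$disposition[unaligned] <- "EXCLUDED_UNASSIGNED"
  bad_conv <- assigned & !unaligned & p$conversion_rate < min_conversion
  p$disposition[bad_conv] <- "EXCLUDED_CONVERSION"
  bad_unrec <- assigned & !unaligned & !bad_conv & grepl("N", p$states, fixed = TRUE)
  p$disposition[bad_unrec] <- "EXCLUDED_UNRECOGNIZED"
  retained <- p$disposition == "ASSIGNED"
  p$disposition[retained] <- "RETAINED"

  counts <- p[retained, c("sample_id", "group", "locus", "states")] |>
    rename(pattern = states) |>
    count(sample_id, group, locus, pattern, name = "count")
  excl <- p[!retained, ] |>
    count(locus, sample_id, disposition, name = "n")
  pattern_table(counts, excl)
}

#' Process amplicon FASTQ files into a pattern table
#'
#' Reads merged amplicon FASTQ, demultiplexes with chimera exclusion, calls
#' CpG states against the design references, applies the conversion-rate
#' and unrecognized-site filters, and aggregates per-molecule pattern
#' counts.
#'
#' @param files character vector of FASTQ paths.
#' @param design an [amplicon_design()].
#' @param min_conversion retention threshold on the per-read conversion
#'   rate.
#' @return a [pattern_table()]; exclusion tallies are available via
#'   [exclusion_tallies()].
#' @export
process_reads <- function(files, design, min_conversion = 0.95) {
  seqs <- unlist(lapply(files, function(f) {
    as.character(Biostrings::readDNAStringSet(f, format = "fastq"))
  }), use.names = FALSE)
  dm <- demultiplex(seqs, design)
  dm$states <- NA_character_
  dm$conversion_rate <- NA_real_
  for (loc in names(design$loci)) {
    idx <- which(dm$locus == loc & dm$disposition == "ASSIGNED")
    if (length(idx) == 0) next
    called <- call_methylation(dm$seq[idx], design$loci[[loc]])
    dm$states[idx] <- called$states
    dm$conversion_rate[idx] <- ifelse(called$aligned,
                                      called$conversion_rate, NA_real_)
  }
  filter_reads(dm[, c("sample_id", "group", "locus", "states",
                      "conversion_rate", "disposition")],
               min_conversion = min_conversion)
}

#' Merge a read pair into a single amplicon sequence
#'
#' Finds the overlap offset of the reverse-complemented mate maximising the
#' number of matching bases; overlap mismatches are resolved by the higher
#' base quality, ties by read 1.  Pairs whose best overlap is shorter than
#' `min_overlap` or less than 75% identical are rejected.
#'
#' @param read1,read2 mate sequences (read 2 in sequencing orientation).
#' @param qual1,qual2 optional quality strings (Phred+33).
#' @param min_overlap minimum acceptable overlap length.
#' @return list with `merged` (sequence or `NA`) and `reason`
#'   (`"MERGED"` or `"EXCLUDED_NO_OVERLAP"`).
#' @export
merge_pairs <- function(read1, read2, qual1 = NULL, qual2 = NULL,
                        min_overlap = 20L) {
  r2 <- rc_dna(read2)
  q1 <- if (is.null(qual1)) strrep("I", nchar(read1)) else qual1
  q2 <- if (is.null(qual2)) strrep("I", nchar(read2)) else
    paste(rev(strsplit(qual2, "")[[1]]), collapse = "")
  a <- strsplit(read1, "")[[1]]; b <- strsplit(r2, "")[[1]]
  qa <- utf8ToInt(q1); qb <- utf8ToInt(q2)
  n1 <- length(a); n2 <- length(b)
  best <- list(score = -1L, off = NA_integer_)
  for (off in 0:(n1 - min_overlap)) {
    ov <- min(n1 - off, n2)
    if (ov < min_overlap) break
    hits <- sum(a[off + seq_len(ov)] == b[seq_len(ov)])
    if (hits / ov >= 0.75 && hits > best$score) {
      best <- list(score = hits, off = off, ov = ov)
    }
  }
  if (is.na(best$off)) {
    return(list(merged = NA_character_, reason = "EXCLUDED_NO_OVERLAP"))
  }
  off <- best$off; ov <- best$ov
  cons <- b[seq_len(ov)]
  i1 <- off + seq_len(ov)
  use1 <- a[i1] == cons | qa[i1] >= qb[seq_len(ov)]  # tie -> read1
  cons[use1] <- a[i1][use1]
  merged <- paste(c(a[seq_len(off)], cons,
                    if (n2 > ov) b[(ov + 1):n2]), collapse = "")
  list(merged = merged, reason = "MERGED")
}
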