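# Synthetic cohort generation.
#
# Two paths share one molecule model: simulate_pattern_cohort() draws
# per-molecule CpG states and applies the noise processes directly to the
# state vectors (fast; used for statistical work at full coverage), while
# simulate_cohort() additionally serialises every molecule to a barcoded
# FASTQ read so the read-processing stage can be exercised end to end.

jitter_weights <- function(w, sdlog) {
  if (sdlog <= 0) return(w)
  w2 <- w * exp(rnorm(length(w), 0, sdlog))
  w2 / sum(w2)
}

# draw n molecules from the (group, locus) mixture; returns logical matrix
# n x n_cpg (TRUE = methylated) in class order plus the class index
draw_molecules <- function(model, group, locus, n, sdlog = model$dispersion_sdlog) {
  cls <- model$classes[model$classes$group == group &
                         model$classes$locus == locus, ]
  if (nrow(cls) == 0) abort_schema(sprintf("no classes for %s/%s", group, locus))
  w <- jitter_weights(cls$weight, sdlog)
  counts <- as.vector(rmultinom(1, n, w))
  n_cpg <- length(cls$probs[[1]])
  M <- matrix(FALSE, nrow = n, ncol = n_cpg)
  at <- 0L
  for (k in seq_len(nrow(cls))) {
    if (counts[k] == 0) next
    idx <- at + seq_len(counts[k])
    p <- cls$probs[[k]]
    if (all(p %in% c(0, 1))) {
      M[idx, ] <- matrix(rep(p == 1, each = counts[k]), nrow = counts[k])
    } else {
      M[idx, ] <- matrix(rbinom(counts[k] * n_cpg, 1,
                                rep(p, each = counts[k])) == 1,
                         nrow = counts[k])
    }
    at <- at + counts[k]
  }
  M
}

state_strings <- function(M) {
  ch <- matrix("T", nrow = nrow(M), ncol = ncol(M))
  ch[M] <- "C"
  do.call(paste0, asplit(ch, 2))
}

#' Simulate a cohort directly at the methylation-pattern level
#'
#' Draws molecules for every sample and locus of the design, applies the
#' model's noise processes to the CpG state vectors and the per-read
#' conversion-rate filter, and returns the resulting [pattern_table()]
#' together with the pre-noise ground truth.  Distributionally this matches
#' running [simulate_cohort()] followed by [process_reads()], minus the
#' FASTQ serialisation (barcodes, chimeras, alignment).
#'
#' @param model an [epiallele_model()].
#' @param design an [amplicon_design()].
#' @param reads_per_sample fixed reads per sample x locus; default `NULL`
#'   draws uniformly from `model$coverage_range`.
#' @param min_conversion per-read conversion-rate retention threshold
#'   (inclusive).
#' @param seed optional integer seed for reproducibility.
#' @return list with elements `table` (a [pattern_table()]) and `truth`
#'   (tibble `sample_id`, `group`, `locus`, `pattern`, `count` of pre-noise
#'   molecules).
#' @export
simulate_pattern_cohort <- function(model, design, reads_per_sample = NULL,
                                    min_conversion = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  samples <- design$scheme$samples
  counts <- list(); truths <- list(); excl <- list()
  se <- model$sequencing_error_rate
  ic <- model$inappropriate_conversion_rate
  cf <- model$conversion_failure_rate
  for (loc in names(design$loci)) {
    spec <- design$loci[[loc]]
    n_cpg <- length(spec$cpg_positions)
    n_c <- length(non_cpg_c_positions(spec))
    p_not_t <- cf + (1 - cf) * se  # non-CpG C read as anything but T
    for (r in seq_len(nrow(samples))) {
      sid <- samples$sample_id[r]; grp <- samples$group[r]
      n <- reads_per_sample %||%
        sample(seq(model$coverage_range[1], model$coverage_range[2]), 1)
      M <- draw_molecules(model, grp, loc, n)
      tb <- table(state_strings(M))
      truths[[length(truths) + 1L]] <-
        tibble(sample_id = sid, group = grp, locus = loc,
               pattern = names(tb), count = as.integer(tb))
      # noise on CpG states
      if (ic > 0 && any(M)) {
        flip <- M & matrix(runif(length(M)) < ic, nrow = n)
        M[flip] <- FALSE
      }
      unrec <- matrix(FALSE, nrow = n, ncol = n_cpg)
      if (se > 0) {
        u <- matrix(runif(length(M)), nrow = n)
        state_flip <- u < se / 3          # C<->T substitution
        unrec <- u >= se / 3 & u < se     # substitution to A/G
        M <- xor(M, state_flip)
      }
      # conversion-rate filter from unconverted / miscalled non-CpG Cs
      k_bad <- rbinom(n, n_c, p_not_t)
      conv <- 1 - k_bad / n_c
      bad_conv <- conv < min_conversion
      bad_unrec <- !bad_conv & rowSums(unrec) > 0
      keep <- !bad_conv & !bad_unrec
      tb <- table(state_strings(M[keep, , drop = FALSE]))
      counts[[length(counts) + 1L]] <-
        tibble(sample_id = sid, group = grp, locus = loc,
               pattern = names(tb), count = as.integer(tb))
      excl[[length(excl) + 1L]] <- tibble(
        locus = loc, sample_id = sid,
        disposition = c("EXCLUDED_CONVERSION", "EXCLUDED_UNRECOGNIZED"),
        n = c(sum(bad_conv), sum(bad_unrec)))
    }
  }
  excl <- bind_rows(excl) |> filter(n > 0)
  list(table = pattern_table(bind_rows(counts), excl),
       truth = bind_rows(truths))
}

# converted sense-strand template of a locus: non-CpG C -> T, CpGs tagged
converted_template <- function(spec) {
  tpl <- spec$reference_sequence
  for (q in non_cpg_c_positions(spec)) substr(tpl, q, q) <- "T"
  tpl
}

#' Simulate dual-barcoded bisulfite amplicon FASTQ reads
#'
#' Serialises molecules drawn from the model into merged amplicon reads:
#' sample X/Y barcodes on the ends (in the locus's orientation), the
#' bisulfite-converted insert in between, per-base noise, a configurable
#' fraction of reads emitted as reverse complements, and chimeric reads
#' carrying barcode pairs never assigned to a sample.  Fully reproducible
#' from `seed`.
#'
#' @inheritParams simulate_pattern_cohort
#' @param dir output directory; one FASTQ per locus (`<locus>.fastq`).
#' @param rc_fraction fraction of reads written as reverse complements.
#' @return list: `files` (named FASTQ paths), `truth` (pre-noise pattern
#'   counts per sample x locus, chimeras excluded), `n_reads` (tibble of
#'   emitted read counts per locus).
#' @export
simulate_cohort <- function(model, design, dir = tempfile("cohort"),
                            reads_per_sample = NULL, rc_fraction = 0.5,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- design$scheme$samples
  scheme <- design$scheme
  chim_pairs <- enumerate_chimeric_pairs(scheme)
  se <- model$sequencing_error_rate
  ic <- model$inappropriate_conversion_rate
  cf <- model$conversion_failure_rate
  files <- character(0); truths <- list(); nr <- list()

  for (loc in names(design$loci)) {
    spec <- design$loci[[loc]]
    n_cpg <- length(spec$cpg_positions)
    cpg_pos <- spec$cpg_positions
    ncc <- non_cpg_c_positions(spec)
    tpl <- converted_template(spec)
    all_seq <- character(0)
    for (r in seq_len(nrow(samples))) {
      sid <- samples$sample_id[r]; grp <- samples$group[r]
      n <- reads_per_sample %||%
        sample(seq(model$coverage_range[1], model$coverage_range[2]), 1)
      M <- draw_molecules(model, grp, loc, n)
      chim <- runif(n) < model$chimera_rate
      truths[[length(truths) + 1L]] <-
        tibble(sample_id = sid, group = grp, locus = loc,
               pattern = state_strings(M[!chim, , drop = FALSE])) |>
        count(sample_id, group, locus, pattern, name = "count")
      # build inserts from the converted template
      ins <- rep(tpl, n)
      for (k in seq_len(n_cpg)) {
        p <- cpg_pos[k]
        unmeth <- !M[, k]
        if (ic > 0) {
          mis <- M[, k] & runif(n) < ic
          unmeth <- unmeth | mis
        }
        idx <- which(unmeth)
        if (length(idx)) substr(ins[idx], p, p) <- "T"
        # template already carries C at CpG positions
      }
      if (cf > 0) {
        for (q in ncc) {
          idx <- which(runif(n) < cf)
          if (length(idx)) substr(ins[idx], q, q) <- "C"
        }
      }
      if (se > 0) {
        L <- nchar(tpl)
        e <- rbinom(n, L, se)
        while (any(e > 0)) {
          idx <- which(e > 0)
          pos <- sample.int(L, length(idx), replace = TRUE)
          old <- substr(ins[idx], pos, pos)
          new <- vapply(old, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                        character(1), USE.NAMES = FALSE)
          substr(ins[idx], pos, pos) <- new
          e[idx] <- e[idx] - 1L
        }
      }
      # barcodes in locus orientation
      x_seq <- scheme$forward_codes[[samples$x_code[r]]]
      y_seq <- scheme$reverse_codes[[samples$y_code[r]]]
      if (any(chim)) {
        pick <- chim_pairs[sample.int(nrow(chim_pairs), sum(chim), replace = TRUE), ]
        xs <- rep(x_seq, n); ys <- rep(y_seq, n)
        xs[chim] <- scheme$forward_codes[pick$x_code]
        ys[chim] <- scheme$reverse_codes[pick$y_code]
      } else {
        xs <- x_seq; ys <- y_seq
      }
      fwd <- if (spec$forward_end == "X") xs else ys
      rev_ <- if (spec$forward_end == "X") ys else xs
      all_seq <- c(all_seq, paste0(fwd, ins, rc_dna(rev_)))
    }
    # shuffle and flip orientation for part of the pool
    all_seq <- all_seq[sample.int(length(all_seq))]
    flip <- runif(length(all_seq)) < rc_fraction
    all_seq[flip] <- rc_dna(all_seq[flip])
    path <- file.path(dir, paste0(loc, ".fastq"))
    ids <- sprintf("@%s:%07d", loc, seq_along(all_seq))
    qual <- strrep("I", nchar(all_seq))
    readr::write_lines(c(rbind(ids, all_seq, "+", qual)), path)
    files[loc] <- path
    nr[[length(nr) + 1L]] <- tibble(locus = loc, n_reads = length(all_seq))
  }
  list(files = files, truth = bind_rows(truths), n_reads = bind_rows(nr))
}

#' Simulate low-coverage WGBS-style per-read CpG call tables
#'
#' Emulates short-read whole-genome bisulfite data over one amplicon locus:
#' each fragment covers a contiguous window shorter than the insert, so only
#' a subset of CpG indices is observed per read.  Reads are labelled
#' `normal` or `cancer`; each label borrows the mixture of one model group.
#'
#' @param model an [epiallele_model()].
#' @param locus a [locus_spec()].
#' @param read_length_bp fragment window length; must be shorter than the
#'   span needed to cover all CpGs.
#' @param n_fragments fragments per sample.
#' @param n_samples named integer vector, samples per output group.
#' @param group_models named character vector mapping output groups to model
#'   groups.
#' @param seed optional integer seed.
#' @return tibble with columns `read_id`, `sample_id`, `group`,
#'   `covered` (comma-separated CpG indices) and `states` (same-length
#'   string over C/T).
#' @export
simulate_wgbs_reads <- function(model, locus, read_length_bp = 70,
                                n_fragments = 40,
                                n_samples = c(normal = 7, cancer = 11),
                                group_models = c(normal = "HD", cancer = "PCa"),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cpg <- locus$cpg_positions
  if (read_length_bp >= max(cpg) - min(cpg) + 2) {
    abort_schema("read_length_bp must be short enough to leave CpGs uncovered")
  }
  ic <- model$inappropriate_conversion_rate
  se <- model$sequencing_error_rate
  out <- list()
  serial <- 0L
  for (g in names(n_samples)) {
    for (s in seq_len(n_samples[[g]])) {
      sid <- sprintf("%s%02d", g, s)
      M <- draw_molecules(model, group_models[[g]], locus$name, n_fragments)
      # noise on true states, as in the pattern path
      if (ic > 0 && any(M)) M[M & matrix(runif(length(M)) < ic, nrow = nrow(M))] <- FALSE
      if (se > 0) M <- xor(M, matrix(runif(length(M)) < se / 3, nrow = nrow(M)))
      for (f in seq_len(n_fragments)) {
        repeat {
          start <- sample(seq(min(cpg) - read_length_bp + 1, max(cpg)), 1)
          cov <- which(cpg >= start & cpg <= start + read_length_bp - 1)
          if (length(cov) > 0) break
        }
        serial <- serial + 1L
        out[[serial]] <- tibble(
          read_id = sprintf("wgbs%06d", serial),
          sample_id = sid, group = g,
          covered = paste(cov, collapse = ","),
          states = paste(ifelse(M[f, cov], "C", "T"), collapse = "")
        )
      }
    }
  }
  bind_rows(out)
}

#' Write / read a WGBS per-read call table as TSV
#' @param obs tibble as returned by [simulate_wgbs_reads()].
#' @param path TSV file path.
#' @return `path` (write) or the tibble (read).
#' @export
write_wgbs_table <- function(obs, path) {
  readr::write_tsv(obs, path)
  invisible(path)
}

#' @rdname write_wgbs_table
#' @export
read_wgbs_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    read_id = readr::col_character(), sample_id = readr::col_character(),
    group = readr::col_character(), covered = readr::col_character(),
    states = readr::col_character()))
}
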