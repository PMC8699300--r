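#' Describe one amplicon locus
#'
#' A locus is a bisulfite PCR amplicon on the genomic sense strand, with its
#' CpG cytosines indexed 1..n in 5'->3' order.  Coordinates are 1-based and
#' refer to `reference_sequence`, which spans the full insert (primer binding
#' sites included, sample barcodes excluded).
#'
#' @param name locus (gene) name, e.g. `"GSTP1"`.
#' @param reference_sequence genomic-sense nucleotide string of the amplicon
#'   insert, without barcodes.
#' @param cpg_positions strictly increasing 1-based offsets of the CpG
#'   cytosines in `reference_sequence`.
#' @param primer_forward,primer_reverse primer sequences as synthesised
#'   (opaque strings; the reverse primer anneals to the sense strand, so the
#'   insert ends with its reverse complement).
#' @param forward_end which barcode family (`"X"` or `"Y"`) sits on the
#'   forward primer for this locus; the other family sits on the reverse
#'   primer.
#'
#' @return an object of class `locus_spec`.
#' @export
locus_spec <- function(name, reference_sequence, cpg_positions,
                       primer_forward, primer_reverse,
                       forward_end = c("X", "Y")) {
  forward_end <- match.arg(forward_end)
  spec <- structure(
    list(
      name = as.character(name),
      reference_sequence = toupper(reference_sequence),
      cpg_positions = as.integer(cpg_positions),
      primer_forward = toupper(primer_forward),
      primer_reverse = toupper(primer_reverse),
      insert_length_bp = nchar(reference_sequence),
      forward_end = forward_end
    ),
    class = "locus_spec"
  )
  validate_locus_spec(spec)
  spec
}

validate_locus_spec <- function(spec) {
  pos <- spec$cpg_positions
  if (length(pos) == 0 || any(diff(pos) <= 0)) {
    abort_schema(sprintf("locus %s: cpg_positions must be strictly increasing",
                         spec$name))
  }
  if (any(pos < 1) || any(pos + 1L > spec$insert_length_bp)) {
    abort_cpg_site(sprintf("locus %s: CpG position outside the reference",
                           spec$name))
  }
  di <- substring(spec$reference_sequence, pos, pos + 1L)
  if (!all(di == "CG")) {
    abort_cpg_site(sprintf(
      "locus %s: positions %s do not point at a CG dinucleotide",
      spec$name, paste(pos[di != "CG"], collapse = ", ")
    ))
  }
  if (spec$insert_length_bp != nchar(spec$reference_sequence)) {
    abort_schema(sprintf("locus %s: insert_length_bp mismatch", spec$name))
  }
  invisible(spec)
}

#' Non-CpG cytosine positions of a locus reference
#'
#' These are the positions whose conversion status defines the per-read
#' bisulfite conversion rate: an unmethylated non-CpG cytosine must read as T
#' after conversion and PCR.
#'
#' @param spec a [locus_spec()].
#' @return integer vector of 1-based positions.
#' @export
non_cpg_c_positions <- function(spec) {
  all_c <- which(strsplit(spec$reference_sequence, "", fixed = TRUE)[[1]] == "C")
  setdiff(all_c, spec$cpg_positions)
}

#' Dual-index barcode scheme
#'
#' Samples are encoded by an (X, Y) pair of 8-mers, one on each primer.
#' Barcode pairs never used in library construction identify chimeric
#' molecules formed during pooled PCR/sequencing, which are excluded.
#'
#' @param forward_codes named character vector of X-codes (names `X1`, ...).
#' @param reverse_codes named character vector of Y-codes (names `Y1`, ...).
#' @param samples a data frame with columns `sample_id`, `group` (one of
#'   `"HD"`, `"BPH"`, `"PCa"`), `x_code`, `y_code`.
#'
#' @return an object of class `barcode_scheme`.
#' @export
barcode_scheme <- function(forward_codes, reverse_codes, samples) {
  samples <- as_tibble(samples)
  scheme <- structure(
    list(
      forward_codes = forward_codes,
      reverse_codes = reverse_codes,
      samples = samples
    ),
    class = "barcode_scheme"
  )
  validate_barcode_scheme(scheme)
  scheme
}

validate_barcode_scheme <- function(scheme) {
  for (fam in c("forward_codes", "reverse_codes")) {
    codes <- scheme[[fam]]
    if (any(nchar(codes) != 8)) {
      abort_schema(sprintf("%s: all barcodes must be 8-mers", fam))
    }
    if (anyDuplicated(codes)) {
      abort_duplicate_barcode(sprintf("%s: duplicated barcode sequence", fam))
    }
  }
  s <- scheme$samples
  need <- c("sample_id", "group", "x_code", "y_code")
  if (!all(need %in% names(s))) {
    abort_schema("samples must have columns sample_id, group, x_code, y_code")
  }
  if (!all(s$group %in% c("HD", "BPH", "PCa"))) {
    abort_schema("sample groups must be HD, BPH or PCa")
  }
  if (anyDuplicated(s$sample_id)) {
    abort_duplicate_assignment("duplicated sample id")
  }
  if (!all(s$x_code %in% names(scheme$forward_codes)) ||
      !all(s$y_code %in% names(scheme$reverse_codes))) {
    abort_schema("sample assignment refers to an unknown barcode label")
  }
  if (anyDuplicated(paste(s$x_code, s$y_code))) {
    abort_duplicate_assignment("an (X, Y) barcode pair is assigned twice")
  }
  # chimera guard: tumor-group and healthy-donor libraries share no codes
  pca <- s[s$group == "PCa", ]
  hd <- s[s$group == "HD", ]
  if (length(intersect(pca$x_code, hd$x_code)) > 0 ||
      length(intersect(pca$y_code, hd$y_code)) > 0) {
    abort_schema("PCa and HD samples must not share barcode codes")
  }
  invisible(scheme)
}

#' Assemble a validated amplicon study design
#'
#' @param loci list of [locus_spec()] objects.
#' @param scheme a [barcode_scheme()].
#' @return an object of class `amplicon_design`.
#' @export
amplicon_design <- function(loci, scheme) {
  names(loci) <- vapply(loci, `[[`, character(1), "name")
  design <- structure(list(loci = loci, scheme = scheme),
                      class = "amplicon_design")
  for (l in loci) validate_locus_spec(l)
  validate_barcode_scheme(scheme)
  design
}

#' @export
print.amplicon_design <- function(x, ...) {
  cat("<amplicon_design>\n")
  for (l in x$loci) {
    cat(sprintf("  %-10s %3d bp, %2d CpGs, %s-codes on forward primer\n",
                l$name, l$insert_length_bp, length(l$cpg_positions),
                l$forward_end))
  }
  cat(sprintf("  %d samples (%s)\n", nrow(x$scheme$samples),
              paste(sprintf("%s=%d", names(table(x$scheme$samples$group)),
                            table(x$scheme$samples$group)), collapse = ", ")))
  invisible(x)
}

#' Barcode pairs used in library construction
#'
#' The complement of this set over the full X-by-Y grid defines chimeric
#' pairs: molecules carrying a pair never used in any library are artifacts
#' and are excluded from analysis.
#'
#' @param scheme a [barcode_scheme()].
#' @return tibble with columns `x_code`, `y_code`.
#' @export
enumerate_valid_pairs <- function(scheme) {
  distinct(scheme$samples[, c("x_code", "y_code")])
}

#' All chimeric (unused) barcode pairs
#'
#' @param scheme a [barcode_scheme()].
#' @return tibble with columns `x_code`, `y_code`.
#' @export
enumerate_chimeric_pairs <- function(scheme) {
  grid <- tidyr::expand_grid(x_code = names(scheme$forward_codes),
                             y_code = names(scheme$reverse_codes))
  dplyr::anti_join(grid, enumerate_valid_pairs(scheme),
                   by = c("x_code", "y_code"))
}

#' Read a study design from a JSON or YAML file
#'
#' The schema mirrors the constructors: a `loci` list (fields of
#' [locus_spec()]) and a `barcodes` block with `X`, `Y` named code maps and a
#' `samples` table.  All design invariants are re-validated on load.
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return an [amplicon_design()].
#' @export
load_design <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(cfg) || is.null(cfg$loci) || is.null(cfg$barcodes)) {
    abort_schema("design file must contain 'loci' and 'barcodes' blocks")
  }
  loci <- lapply(cfg$loci, function(l) {
    need <- c("name", "reference_sequence", "cpg_positions",
              "primer_forward", "primer_reverse", "forward_end")
    if (!all(need %in% names(l))) {
      abort_schema(paste("locus block missing fields:",
                         paste(setdiff(need, names(l)), collapse = ", ")))
    }
    spec <- locus_spec(l$name, l$reference_sequence,
                       unlist(l$cpg_positions),
                       l$primer_forward, l$primer_reverse, l$forward_end)
    if (!is.null(l$insert_length_bp) &&
        l$insert_length_bp != spec$insert_length_bp) {
      abort_schema(sprintf("locus %s: declared insert_length_bp %d != %d",
                           l$name, l$insert_length_bp, spec$insert_length_bp))
    }
    spec
  })
  b <- cfg$barcodes
  samples <- bind_rows(lapply(b$samples, as_tibble))
  scheme <- barcode_scheme(unlist(b$X), unlist(b$Y), samples)
  amplicon_design(loci, scheme)
}

#' Write a study design to JSON or YAML
#'
#' Round-trips with [load_design()].
#'
#' @param design an [amplicon_design()].
#' @param path output file ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  cfg <- list(
    loci = lapply(unname(design$loci), function(l) {
      list(name = l$name,
           reference_sequence = l$reference_sequence,
           cpg_positions = l$cpg_positions,
           primer_forward = l$primer_forward,
           primer_reverse = l$primer_reverse,
           insert_length_bp = l$insert_length_bp,
           forward_end = l$forward_end)
    }),
    barcodes = list(
      X = as.list(design$scheme$forward_codes),
      Y = as.list(design$scheme$reverse_codes),
      samples = lapply(seq_len(nrow(design$scheme$samples)), function(i) {
        as.list(design$scheme$samples[i, ])
      })
    )
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Export reference amplicon inserts as FASTA
#'
#' @param design an [amplicon_design()].
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(design, path) {
  seqs <- Biostrings::DNAStringSet(
    setNames(vapply(design$loci, `[[`, character(1), "reference_sequence"),
             names(design$loci))
  )
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
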