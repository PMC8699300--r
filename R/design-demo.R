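# Bundled demonstration design.
#
# The three loci mirror the published assay geometry -- GSTP1 (142 bp insert,
# 17 CpGs), RNF219 (161 bp, 17 CpGs) and KIAA1539 (89 bp, 5 CpGs), with the
# X-codes on the reverse primer for GSTP1/RNF219 and on the forward primer
# for KIAA1539 -- but the reference inserts are SYNTHETIC sequences fabricated
# to those lengths and CpG counts.  The true amplicon sequences are not
# published, so nothing here asserts real genomic sequence; the fabricated
# inserts exist only to make the repository self-contained and the pipeline
# fully testable.

.demo_refs <- list(
  RNF219 = list(
    ref = paste0(
      "GTGATTGTGGGTATAGTTATAAAATCGTCTGCGTTCGGTCATCAACTTCATAACGGGCGAACGACGACGA",
      "ATCTACGATACGTTGCGTCAAAACGTCATCGACATCTGAACATCTGCGTCGACGGTGCTGCGGATCTACA",
      "TTTTTGGGAGATGGGGGTAGT"),
    cpg = c(26L, 32L, 36L, 54L, 58L, 62L, 65L, 68L, 76L, 81L, 86L, 94L,
            100L, 117L, 120L, 123L, 131L),
    fwd = "GTGATTGTGGGTATAGTTATAAAA", rev = "ACTACCCCCATCTCCCAAAA",
    forward_end = "Y"
  ),
  KIAA1539 = list(
    ref = paste0(
      "AGGAAGGAGGAGATAAAGTGATTCGGACAACGTCGATCAACTTCTGCGACTTACAACTTCATCGTTGTGT",
      "GATGATAAGTTTAGAGGGG"),
    cpg = c(24L, 31L, 34L, 47L, 63L),
    fwd = "AGGAAGGAGGAGATAAAGTGAT", rev = "CCCCTCTAAACTTATCATCACA",
    forward_end = "X"
  ),
  GSTP1 = list(
    ref = paste0(
      "ATTTGGGAAAGAGGGAAAGGTTGCAAATTGATCTGCGAGCGGACGTGCTGCGGCGGCAAAGCGGCGACTT",
      "CGACAGCGACGGACTGCGACGACGACGTGCGAAGCAACGTCGTCTACAATCAACTGGGATTTTTTAGAAG",
      "AG"),
    cpg = c(36L, 40L, 44L, 51L, 54L, 62L, 65L, 71L, 77L, 80L, 87L, 90L,
            93L, 96L, 100L, 108L, 111L),
    fwd = "ATTTGGGAAAGAGGGAAAGGTT", rev = "CTCTTCTAAAAAATCC",
    forward_end = "Y"
  )
)

.demo_x_codes <- c(
  X1 = "TAGATCGC", X2 = "CTCTCTAT", X3 = "TATCCTCT", X4 = "AGAGTAGA",
  X5 = "ACTGCATA", X6 = "AAGGAGTA", X7 = "CTAAGCCT", X8 = "CCTCTCTG"
)
.demo_y_codes <- c(
  Y1 = "TCGCCTTA", Y2 = "CTAGTACG", Y3 = "TTCTGCCT", Y4 = "GCTCAGGA",
  Y5 = "AGGAGTCC", Y6 = "CATGCCTA", Y7 = "GTAGAGAG", Y8 = "CCTCTCTG",
  Y9 = "AGCGTAGC", Y10 = "CAGCCTCG", Y11 = "TGCCTCTT", Y12 = "TCCTCTAC"
)

#' Bundled demonstration study design
#'
#' Three loci with the published assay geometry (insert lengths, CpG counts,
#' barcode orientation, the 8 X- and 12 Y-barcodes) over a cohort of 20 PCa,
#' 17 BPH and 18 HD samples.  The reference inserts are synthetic stand-ins
#' fabricated to the printed lengths and CpG counts; see the package vignette.
#' Barcode pairs are allocated so that the PCa and HD libraries share no
#' codes, which makes cross-group chimeric molecules detectable.
#'
#' @return an [amplicon_design()].
#' @export
#' @examples
#' d <- demo_design()
#' length(d$loci)
#' nrow(enumerate_valid_pairs(d$scheme))
demo_design <- function() {
  loci <- lapply(names(.demo_refs), function(nm) {
    r <- .demo_refs[[nm]]
    locus_spec(nm, r$ref, r$cpg, r$fwd, r$rev, r$forward_end)
  })
  # PCa: X1-X4 x Y1-Y5 (20); HD: X5-X8 x Y6-Y10 (first 18);
  # BPH: X1-X8 x Y11-Y12 (16) plus (X5, Y1) -- BPH may share codes with
  # either group, PCa and HD never share any.
  pca <- tidyr::expand_grid(x_code = paste0("X", 1:4),
                            y_code = paste0("Y", 1:5))
  hd <- tidyr::expand_grid(x_code = paste0("X", 5:8),
                           y_code = paste0("Y", 6:10))[1:18, ]
  bph <- bind_rows(
    tidyr::expand_grid(x_code = paste0("X", 1:8),
                       y_code = paste0("Y", 11:12)),
    tibble(x_code = "X5", y_code = "Y1")
  )
  samples <- bind_rows(
    mutate(pca, group = "PCa",
           sample_id = sprintf("PCa%02d", row_number())),
    mutate(bph, group = "BPH",
           sample_id = sprintf("BPH%02d", row_number())),
    mutate(hd, group = "HD",
           sample_id = sprintf("HD%02d", row_number()))
  )[, c("sample_id", "group", "x_code", "y_code")]
  scheme <- barcode_scheme(.demo_x_codes, .demo_y_codes, samples)
  amplicon_design(loci, scheme)
}
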