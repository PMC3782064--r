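#' Packaged recurrent-duplication call fixture
#'
#' The seven heterozygous duplication calls (copy number 3) at the OVOS2
#' locus on chr12p11.21 carried by seven cases, with their printed probe
#' counts, confidences and jittered boundaries. Merging them yields a
#' single region chr12:31152226-31300846 of span length 148,621 bp.
#'
#' @return `GRanges` of 7 CNV calls.
#' @export
fixtureTable6Ovos2 <- function() {
  makeCnvCalls(
    chrom = rep("12", 7),
    start = c(31152226, 31152226, 31157554, 31157554, 31157554,
              31180151, 31180151),
    end = c(31298174, 31300846, 31298174, 31298174, 31298174,
            31298174, 31298174),
    sample_id = c("PD31", "PD18", "PD3", "PD20", "PD72", "PD67", "PD74"),
    num_probes = c(54, 33, 31, 31, 53, 52, 52),
    copy_number = rep(3L, 7),
    confidence = c(52.8, 84.3, 95.9, 77.4, 177.6, 82.6, 120.2))
}

#' Packaged carrier contingency tables
#'
#' 2x2 carrier tables (case carriers, case non-carriers; control carriers,
#' control non-carriers) for a 261-case / 171-control study: the deletion,
#' homozygous-deletion, heterozygous-deletion, duplication and any-CNV
#' carrier counts of the full >=100 kb call set (`all_*`) and of the rare
#' subset (`rare_*`). Non-carrier cells are the group sizes minus the
#' carrier counts.
#'
#' @return named list of 2x2 integer matrices with dimnames.
#' @export
fixtureCarrierTables <- function() {
  tab <- function(case_with, ctrl_with, n_case = 261L, n_ctrl = 171L) {
    matrix(c(case_with, n_case - case_with, ctrl_with, n_ctrl - ctrl_with),
           nrow = 2, byrow = TRUE,
           dimnames = list(c("case", "control"),
                           c("carrier", "non_carrier")))
  }
  list(
    all_deletion = tab(193L, 125L),
    all_homozygous_deletion = tab(51L, 23L),
    all_heterozygous_deletion = tab(173L, 118L),
    all_duplication = tab(209L, 140L),
    all_total = tab(248L, 158L),
    rare_deletion = tab(115L, 85L),
    rare_homozygous_deletion = tab(1L, 2L),
    rare_duplication = tab(164L, 109L),
    rare_total = tab(203L, 139L))
}

#' Packaged region carrier counts
#'
#' The eleven gene-labelled rare CNV regions with their case/control
#' carrier counts in a 261/171 study, ready as input to [regionFisher()].
#'
#' @return data.frame with `gene`, `position`, `case_with`, `case_without`,
#'   `control_with`, `control_without`.
#' @export
fixtureRegionCounts <- function() {
  d <- data.frame(
    gene = c("CFH", "BCHE", "SDK1", "DLC1", "SGCZ", "CYP2E1", "SYCE1",
             "PPYR1", "ANXA8", "ANXA8L1", "OVOS2"),
    position = c("chr1:194887630-194983257", "chr3:166973385-167037947",
                 "chr7:3307605-4275157", "chr8:12985242-13416766",
                 "chr8:13991743-15140163", "chr10:135190856-135202610",
                 "chr10:135217394-135232866", "chr10:46503539-46508326",
                 "chr10:46577989-46594128", "chr10:46577994-46594046",
                 "chr12:31158726-31250355"),
    case_with = c(3L, 4L, 3L, 3L, 3L, 3L, 3L, 5L, 3L, 3L, 7L),
    stringsAsFactors = FALSE)
  d$case_without <- 261L - d$case_with
  d$control_with <- 0L
  d$control_without <- 171L
  d
}

#' Fixture dataset: one recurrent case-only locus in a 261/171 study
#'
#' The seven packaged duplication calls of [fixtureTable6Ovos2()] embedded
#' in a full sample manifest: 261 cases (the 7 carriers plus 254 CNV-free
#' cases) and 171 CNV-free controls. Running the region association on
#' this dataset reproduces the locus's one-sided Fisher p of 0.0284.
#'
#' @return a [CnvDataset-class].
#' @export
fixtureOvos2Dataset <- function() {
  calls <- fixtureTable6Ovos2()
  case_ids <- c(unique(calls$sample_id),
                sprintf("CASE%04d", seq_len(254L)))
  ctrl_ids <- sprintf("CTRL%04d", seq_len(171L))
  samples <- data.frame(
    sample_id = c(case_ids, ctrl_ids),
    status = rep(c("case", "control"), c(261L, 171L)),
    stringsAsFactors = FALSE)
  CnvDataset(calls, samples)
}
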