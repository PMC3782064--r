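# NCBI36/hg18 autosome lengths (bp), the genome model used for placement
.HG18_AUTOSOMES <- c(
  `1` = 247249719, `2` = 242951149, `3` = 199501827, `4` = 191273063,
  `5` = 180857866, `6` = 170899992, `7` = 158821424, `8` = 146274826,
  `9` = 140273252, `10` = 135374737, `11` = 134452384, `12` = 132349534,
  `13` = 114142980, `14` = 106368585, `15` = 100338915, `16` = 88827254,
  `17` = 78774742, `18` = 76117153, `19` = 63811651, `20` = 62435964,
  `21` = 46944323, `22` = 49691432)

#' Simulation configuration
#'
#' Defines the conditions of a synthetic two-group CNV call set. The
#' defaults emulate an array-CNV case-control study of 261 cases and 171
#' controls with, per sample, a Poisson number (mean 2.9) of rare calls of
#' which ~39% are deletions. Call sizes are the 100 kb detection floor plus
#' a log-normal excess, truncated at 1.75 Mb, giving a median near 155 kb
#' and mean near 205 kb. Calls are placed uniformly on the 22 autosomes
#' with per-sample calls kept disjoint (segment callers emit
#' non-overlapping segments per sample).
#'
#' @param n_cases,n_controls group sizes (defaults 261/171).
#' @param mean_cnv_rate mean rare-CNV calls per sample (default 2.9).
#' @param deletion_fraction fraction of background calls that are
#'   deletions (default 0.39).
#' @param size_meanlog,size_sdlog log-normal parameters of the size excess
#'   above the lower size bound (defaults `log(55000)` and 1.15).
#' @param size_range lower bound (detection floor, added to the log-normal
#'   excess) and upper truncation in bp (default 100 kb - 1.75 Mb).
#' @param genome named vector of chromosome lengths (default hg18
#'   autosomes).
#' @param planted_loci data.frame with columns `chrom`, `start`, `end`,
#'   `type` ("deletion"/"duplication"), `n_case_carriers`,
#'   `n_control_carriers`: recurrent loci planted with known carriers.
#' @param jitter_bp planted-call boundaries are jittered inward uniformly
#'   up to this many bp on each side (default 30,000), emulating the
#'   boundary spread of a recurrent locus across samples.
#' @param case_deletion_size_mult multiplier applied to case-group deletion
#'   sizes (default 1 = null); a group-level planted size effect.
#' @param frac_fail_probes,frac_fail_conf,frac_fail_size fractions of
#'   background calls mutated to violate the probe-count, confidence and
#'   minimum-size QC thresholds (defaults 0).
#' @param frac_in_segdup fraction of background calls placed inside a
#'   segmental duplication (default 0).
#' @param n_genes,n_segdups,n_exclusions sizes of the generated annotation
#'   tracks.
#' @param seed RNG seed; generation is reproducible given the seed.
#' @return a `SimConfig` list.
#' @export
simConfig <- function(n_cases = 261L, n_controls = 171L,
                      mean_cnv_rate = 2.9, deletion_fraction = 0.39,
                      size_meanlog = log(55000), size_sdlog = 1.15,
                      size_range = c(100000, 1750000),
                      genome = .HG18_AUTOSOMES,
                      planted_loci = NULL, jitter_bp = 30000L,
                      case_deletion_size_mult = 1,
                      frac_fail_probes = 0, frac_fail_conf = 0,
                      frac_fail_size = 0, frac_in_segdup = 0,
                      n_genes = 1000L, n_segdups = 150L,
                      n_exclusions = 44L, seed = 1L) {
  stopifnot(n_cases >= 1L, n_controls >= 1L, mean_cnv_rate >= 0,
            deletion_fraction >= 0, deletion_fraction <= 1,
            case_deletion_size_mult > 0)
  if (!is.null(planted_loci)) {
    need <- c("chrom", "start", "end", "type", "n_case_carriers",
              "n_control_carriers")
    stopifnot(all(need %in% colnames(planted_loci)))
    if (any(planted_loci$n_case_carriers > n_cases) ||
        any(planted_loci$n_control_carriers > n_controls)) {
      stop("infeasible planted carrier counts: more carriers than samples")
    }
  }
  structure(as.list(environment()), class = "SimConfig")
}

#' Planted recurrent duplication locus
#'
#' Convenience for a case-only recurrent heterozygous duplication locus on
#' chromosome 12 (envelope chr12:31152226-31300846), carried by
#' `n_case_carriers` cases and no controls — the structure of a recurrent
#' case-only locus with jittered boundaries.
#'
#' @param n_case_carriers number of case carriers (default 7).
#' @param n_control_carriers number of control carriers (default 0).
#' @return a one-row `planted_loci` data.frame for [simConfig()].
#' @export
plantedRecurrentLocus <- function(n_case_carriers = 7L,
                                  n_control_carriers = 0L) {
  data.frame(chrom = "12", start = 31152226L, end = 31300846L,
             type = "duplication",
             n_case_carriers = as.integer(n_case_carriers),
             n_control_carriers = as.integer(n_control_carriers),
             stringsAsFactors = FALSE)
}

# place n intervals of the given sizes uniformly on the genome, avoiding
# (per element) the intervals already in `avoid` for the same sample
.placeCalls <- function(sizes, genome, avoid_by_sample, sample_ids,
                        forbidden = NULL) {
  n <- length(sizes)
  chrom <- character(n)
  start <- integer(n)
  probs <- genome / sum(genome)
  for (i in seq_len(n)) {
    for (try in 1:100) {
      ch <- sample(names(genome), 1L, prob = probs)
      maxs <- genome[[ch]] - sizes[i]
      if (maxs < 1) next
      st <- sample.int(maxs, 1L)
      cand <- c(st, st + sizes[i] - 1L)
      own <- avoid_by_sample[[sample_ids[i]]]
      clash <- FALSE
      if (!is.null(own) && nrow(own) > 0L) {
        same <- own$chrom == ch
        clash <- any(same & own$start <= cand[2] & own$end >= cand[1])
      }
      if (!clash && !is.null(forbidden) && length(forbidden) > 0L) {
        fb <- forbidden[as.character(GenomicRanges::seqnames(forbidden)) ==
                          ch]
        clash <- any(GenomicRanges::start(fb) <= cand[2] &
                       GenomicRanges::end(fb) >= cand[1])
      }
      if (!clash) break
    }
    chrom[i] <- ch
    start[i] <- st
    avoid_by_sample[[sample_ids[i]]] <- rbind(
      avoid_by_sample[[sample_ids[i]]],
      data.frame(chrom = ch, start = st, end = st + sizes[i] - 1L))
  }
  list(chrom = chrom, start = start,
       avoid_by_sample = avoid_by_sample)
}

.randomTrack <- function(n, genome, min_bp, max_bp, labels = NULL) {
  if (n == 0L) {
    g <- GenomicRanges::GRanges()
    g$label <- character(0)
    return(g)
  }
  ch <- sample(names(genome), n, replace = TRUE,
               prob = genome / sum(genome))
  w <- as.integer(round(stats::runif(n, min_bp, max_bp)))
  st <- vapply(seq_len(n), function(i) {
    sample.int(max(1, genome[[ch[i]]] - w[i]), 1L)
  }, 0L)
  gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(st, st + w - 1L))
  gr$label <- if (is.null(labels)) rep(NA_character_, n) else labels
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Generate a synthetic case-control CNV dataset
#'
#' Draws samples (all passing QC metrics), background rare calls,
#' planted recurrent loci with exact carrier counts, optional QC-noise
#' mutations, and companion gene/segmental-duplication/exclusion tracks.
#' Everything is reproducible from `config$seed`: identical configs give
#' identical output.
#'
#' @param config a [simConfig()].
#' @return list with elements `dataset` (a [CnvDataset-class]), `genes`,
#'   `segdups`, `exclusions` (`GRanges` tracks) and `truth` (the
#'   ground-truth manifest: planted carrier assignments and noise-call
#'   indices).
#' @export
simulateCnvDataset <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  genome <- config$genome
  n_case <- config$n_cases
  n_ctrl <- config$n_controls
  ids <- c(sprintf("CASE%04d", seq_len(n_case)),
           sprintf("CTRL%04d", seq_len(n_ctrl)))
  status <- rep(c("case", "control"), c(n_case, n_ctrl))
  samples <- S4Vectors::DataFrame(
    sample_id = ids, status = status,
    sex = sample(c("male", "female"), length(ids), replace = TRUE),
    call_rate = stats::runif(length(ids), 0.9985, 1),
    lrr_sd = stats::runif(length(ids), 0.10, 0.20),
    baf_sd = stats::runif(length(ids), 0.02, 0.10),
    wave_factor = stats::runif(length(ids), -0.03, 0.03))

  planted <- config$planted_loci
  planted_gr <- if (!is.null(planted) && nrow(planted) > 0L) {
    GenomicRanges::GRanges(normalizeChrom(planted$chrom),
                           IRanges::IRanges(planted$start, planted$end))
  } else NULL
  # filter tracks prone to swallowing a planted locus away from it; a
  # planted recurrent locus sitting inside a segdup or an excluded region
  # is not a scenario the generator emulates
  away <- function(gr) {
    if (is.null(planted_gr) || length(gr) == 0L) return(gr)
    gr[!IRanges::overlapsAny(.strip(gr), .strip(planted_gr))]
  }
  # annotation tracks first so noise placement can target segdups
  genes <- .randomTrack(config$n_genes, genome, 10000, 200000,
                        labels = sprintf("GENE%04d",
                                         seq_len(config$n_genes)))
  segdups <- away(.randomTrack(config$n_segdups, genome, 50000, 400000))
  # large blocks, pericentromeric/telomeric in kind
  exclusions <- away(.randomTrack(config$n_exclusions, genome,
                                  1000000, 3000000))

  # background calls: Poisson count per sample
  n_bg <- stats::rpois(length(ids), config$mean_cnv_rate)
  bg_sample <- rep(ids, n_bg)
  bg_status <- rep(status, n_bg)
  ntot <- length(bg_sample)
  is_del <- stats::runif(ntot) < config$deletion_fraction
  sizes <- numeric(ntot)
  for (i in seq_len(ntot)) {
    repeat {
      s <- config$size_range[1] +
        stats::rlnorm(1, config$size_meanlog, config$size_sdlog)
      if (s <= config$size_range[2]) break
    }
    sizes[i] <- s
  }
  # planted group-level size effect on case deletions
  mult <- ifelse(is_del & bg_status == "case",
                 config$case_deletion_size_mult, 1)
  sizes <- pmin(as.integer(round(sizes * mult)), config$size_range[2])
  avoid <- stats::setNames(vector("list", length(ids)), ids)
  # clean background calls stay clear of planted loci and of the tracks
  # that would trip QC (noise knobs relocate calls there on purpose)
  forbidden <- c(.strip(segdups), .strip(exclusions))
  if (!is.null(planted_gr)) {
    forbidden <- c(forbidden, .strip(planted_gr))
  }
  placed <- .placeCalls(sizes, genome, avoid, bg_sample,
                        forbidden = forbidden)
  cn <- ifelse(is_del,
               ifelse(stats::runif(ntot) < 0.05, 0L, 1L),
               ifelse(stats::runif(ntot) < 0.02, 4L, 3L))
  probes <- pmax(5L, stats::rpois(ntot, sizes / 4000))
  conf <- 10 + stats::rexp(ntot, 1 / 40)

  # QC-noise knobs: mutate disjoint random subsets of background calls so
  # each noisy call violates exactly one threshold
  noise <- list()
  pool <- seq_len(ntot)
  pick <- function(frac) {
    k <- round(frac * ntot)
    sel <- if (k > 0 && length(pool) >= k) {
      pool[sample.int(length(pool), k)]
    } else integer(0)
    pool <<- setdiff(pool, sel)
    sel
  }
  noise$fail_probes <- pick(config$frac_fail_probes)
  noise$fail_conf <- pick(config$frac_fail_conf)
  noise$fail_size <- pick(config$frac_fail_size)
  noise$in_segdup <- pick(config$frac_in_segdup)
  if (length(noise$fail_probes)) {
    probes[noise$fail_probes] <- sample(1:4, length(noise$fail_probes),
                                        replace = TRUE)
  }
  if (length(noise$fail_conf)) {
    conf[noise$fail_conf] <- stats::runif(length(noise$fail_conf), 0, 10)
  }
  if (length(noise$fail_size)) {
    sizes[noise$fail_size] <- as.integer(
      stats::runif(length(noise$fail_size), 20000, 99999))
  }
  if (length(noise$in_segdup) && length(segdups) > 0L) {
    for (i in noise$in_segdup) {
      sd_i <- sample.int(length(segdups), 1L)
      placed$chrom[i] <- as.character(
        GenomicRanges::seqnames(segdups)[sd_i])
      # drop the call fully inside the segdup so union coverage is 100%
      sizes[i] <- min(sizes[i], GenomicRanges::width(segdups)[sd_i])
      placed$start[i] <- GenomicRanges::start(segdups)[sd_i]
    }
  }

  chrom <- placed$chrom
  start <- placed$start
  end <- start + as.integer(sizes) - 1L

  # planted recurrent loci with exact carrier counts and jittered bounds
  truth_carriers <- NULL
  if (!is.null(planted) && nrow(planted) > 0L) {
    case_ids <- ids[status == "case"]
    ctrl_ids <- ids[status == "control"]
    for (r in seq_len(nrow(planted))) {
      carriers <- c(sample(case_ids, planted$n_case_carriers[r]),
                    sample(ctrl_ids, planted$n_control_carriers[r]))
      nc <- length(carriers)
      if (nc == 0L) next
      # total shrink per carrier is at most jitter_bp, split randomly
      # between the two ends, so planted calls keep >= envelope - jitter
      # of their length (the boundary spread of a recurrent locus)
      jit <- min(config$jitter_bp,
                 (planted$end[r] - planted$start[r]) %/% 3)
      shrink <- stats::runif(nc, 0, jit)
      at_start <- stats::runif(nc)
      st <- planted$start[r] + as.integer(round(shrink * at_start))
      en <- planted$end[r] -
        as.integer(round(shrink * (1 - at_start)))
      p_sizes <- en - st + 1L
      chrom <- c(chrom, rep(normalizeChrom(planted$chrom[r]), nc))
      start <- c(start, st)
      end <- c(end, en)
      bg_sample <- c(bg_sample, carriers)
      cn <- c(cn, rep(if (planted$type[r] == "deletion") 1L else 3L, nc))
      probes <- c(probes, pmax(5L, stats::rpois(nc, p_sizes / 4000)))
      conf <- c(conf, 10 + stats::rexp(nc, 1 / 40))
      truth_carriers <- rbind(truth_carriers, data.frame(
        locus = sprintf("%s:%d-%d", planted$chrom[r], planted$start[r],
                        planted$end[r]),
        type = planted$type[r], sample_id = carriers,
        status = rep(c("case", "control"),
                     c(planted$n_case_carriers[r],
                       planted$n_control_carriers[r])),
        stringsAsFactors = FALSE))
    }
  }

  calls <- if (length(chrom) > 0L) {
    makeCnvCalls(chrom, start, end, bg_sample, probes, cn, conf)
  } else {
    .emptyCalls()
  }
  list(
    dataset = CnvDataset(calls, samples),
    genes = genes, segdups = segdups, exclusions = exclusions,
    truth = list(planted = truth_carriers, noise = noise,
                 config = config))
}
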