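# Synthetic dechlorinating communities and qPCR plates with known truth.
#
# The stated world: multiple D. mccartyi strains share one 16S rRNA copy
# per genome and differ in binary rdhA complements; relative abundances
# shift under the selective pressure of the amended chlorinated electron
# acceptor (discrete multiplicative transfers); plates carry duplicate
# reactions at two dilutions plus seven-decade ten-fold standard series;
# Cq values follow the log-linear calibration with Gaussian instrument
# noise (default sd 0.15 cycles); reactions below the per-reaction floor
# come up as "no amplification" and are censored at matrix-dependent MDLs.

#' The default 15-gene rdhA tracking panel
#'
#' Named after the characterized (vcrA, bvcA, tceA) and uncharacterized
#' KB-1 assay suite.
#'
#' @return character vector of 15 gene names.
#' @export
default_gene_panel <- function() {
  c("KB1-1", "KB1-4", "KB1-5", "KB1-6_bvcA", "KB1-11", "KB1-12",
    "KB1-14_vcrA", "KB1-15", "KB1-16", "KB1-17", "KB1-18", "KB1-19",
    "KB1-23", "KB1-25", "KB1-27_tceA")
}

#' Generate synthetic strains with binary gene content
#'
#' A core fraction `overlap` of the panel is present in every strain (the
#' genes shared culture-wide); the rest are assigned independently per
#' strain with probability 1/2. Content vectors must be unique; colliding
#' draws are regenerated, and an impossible request (e.g. `overlap = 1`
#' with more than one strain) errors.
#'
#' @param n_strains number of strains (>= 1).
#' @param panel gene name vector.
#' @param overlap core fraction of the panel in `[0, 1]` (default 0.25).
#' @param seed integer seed; fully determines the content.
#' @param acceptors electron acceptors to assign round-robin as each
#'   strain's preferred substrate.
#' @param fit_preferred,fit_other per-transfer growth factors on the
#'   preferred vs non-preferred acceptor.
#' @return list of strains, each with `strain_id`, `gene_content` (named
#'   0/1 vector), `fitness` (named by acceptor).
#' @export
make_strains <- function(n_strains, panel = default_gene_panel(),
                         overlap = 0.25, seed = 1,
                         acceptors = c("TCE", "cDCE", "VC", "DCA"),
                         fit_preferred = 2, fit_other = 0.5) {
  stopifnot(n_strains >= 1, length(panel) >= 1, overlap >= 0, overlap <= 1)
  n_core <- round(overlap * length(panel))
  n_free <- length(panel) - n_core
  if (n_strains > 1 && 2^n_free < n_strains) {
    stop("panel too small to make ", n_strains, " unique strains at overlap ",
         overlap)
  }
  set.seed(seed)
  core <- if (n_core > 0) sample(panel, n_core) else character(0)
  draw <- function() {
    content <- setNames(integer(length(panel)), panel)
    content[core] <- 1L
    free <- setdiff(panel, core)
    content[free] <- sample(0:1, length(free), replace = TRUE)
    if (sum(content) == 0) content[sample(panel, 1)] <- 1L
    content
  }
  strains <- list()
  keys <- character(0)
  tries <- 0L
  while (length(strains) < n_strains) {
    content <- draw()
    key <- paste(content, collapse = "")
    if (key %in% keys) {
      tries <- tries + 1L
      if (tries > 1000L) {
        stop("cannot generate ", n_strains,
             " unique strain contents (overlap too high / panel too small)")
      }
      next
    }
    keys <- c(keys, key)
    s <- length(strains) + 1L
    pref <- acceptors[(s - 1L) %% length(acceptors) + 1L]
    fitness <- setNames(rep(fit_other, length(acceptors)), acceptors)
    fitness[pref] <- fit_preferred
    strains[[s]] <- list(strain_id = paste0("S", s), gene_content = content,
                         fitness = fitness)
  }
  strains
}

#' Simulate abundance dynamics under acceptor selection
#'
#' Discrete serial transfers: after each transfer on acceptor `a`,
#' `abundance'_s` is proportional to `abundance_s * fitness_s(a)`,
#' renormalized to sum to one.
#'
#' @param strains list from [make_strains()].
#' @param acceptor_schedule character vector, the acceptor fed at each
#'   transfer.
#' @param init_abundances starting abundances (default uniform).
#' @return matrix `(transfers + 1) x n_strains` of abundances, row 1 the
#'   initial state.
#' @export
simulate_selection <- function(strains, acceptor_schedule,
                               init_abundances = NULL) {
  k <- length(strains)
  a <- if (is.null(init_abundances)) rep(1 / k, k) else init_abundances
  stopifnot(length(a) == k, all(a >= 0), abs(sum(a) - 1) < 1e-9)
  out <- matrix(NA_real_, length(acceptor_schedule) + 1L, k,
                dimnames = list(NULL, vapply(strains, `[[`, "", "strain_id")))
  out[1L, ] <- a
  for (t in seq_along(acceptor_schedule)) {
    acc <- acceptor_schedule[t]
    f <- vapply(strains, function(s) {
      if (!acc %in% names(s$fitness)) {
        stop("fitness undefined for acceptor '", acc, "'")
      }
      s$fitness[[acc]]
    }, numeric(1))
    a <- a * f
    if (sum(a) <= 0) stop("all fitness zero on acceptor '", acc, "'")
    a <- a / sum(a)
    out[t + 1L, ] <- a
  }
  out
}

#' Bundle the ground truth for a plate simulation
#'
#' @param strains list from [make_strains()].
#' @param abundance_series samples x strains matrix (rows sum to 1,
#'   rownames are sample ids).
#' @param total_16s_per_unit total D. mccartyi 16S copies per unit
#'   (default 1e7 per mL of culture, which together with the default
#'   volumes places undiluted reactions mid-range of the seven-decade
#'   calibrators; see the methods vignette).
#' @param slope,intercept standard-curve parameters shared by all targets
#'   (defaults: 100 % efficiency, intercept 37).
#' @param cq_noise_sd Gaussian Cq noise, cycles (default 0.15).
#' @param seed integer; fully determines the randomness.
#' @param meta [sample_meta()] rows for the samples (default: 50 mL
#'   culture, 50 uL elution, 2 uL template).
#' @param floor_copies_rxn per-reaction floor below which a well reads
#'   "no amplification" (default 10).
#' @return an object of class `rdh_synth_truth`.
#' @export
synthetic_truth <- function(strains, abundance_series,
                            total_16s_per_unit = 1e7,
                            slope = -1 / log10(2), intercept = 37,
                            cq_noise_sd = 0.15, seed = 1, meta = NULL,
                            floor_copies_rxn = 10) {
  stopifnot(is.matrix(abundance_series),
            ncol(abundance_series) == length(strains),
            all(abs(rowSums(abundance_series) - 1) < 1e-9))
  if (is.null(rownames(abundance_series))) {
    rownames(abundance_series) <- paste0("sample", seq_len(nrow(abundance_series)))
  }
  if (is.null(meta)) {
    meta <- sample_meta(rownames(abundance_series), volume_filtered = 10)
  }
  structure(list(strains = strains, abundance_series = abundance_series,
                 total_16s_per_unit = total_16s_per_unit,
                 slope = slope, intercept = intercept,
                 cq_noise_sd = cq_noise_sd, seed = as.integer(seed),
                 meta = meta, floor_copies_rxn = floor_copies_rxn),
            class = "rdh_synth_truth")
}

#' True rdhA/16S ratio matrix implied by a truth object
#'
#' @param truth an `rdh_synth_truth`.
#' @return genes x samples matrix of content %*% abundances.
#' @export
true_ratio_matrix <- function(truth) {
  content <- vapply(truth$strains, `[[`,
                    truth$strains[[1]]$gene_content, "gene_content")
  content %*% t(truth$abundance_series)
}

#' Simulate a qPCR plate from a synthetic community
#'
#' Per sample and target: true copies per unit are scaled to copies per
#' reaction through the sample's volumes, read out at dilutions 1 and 10
#' in duplicate through the standard curve plus Gaussian Cq noise, and
#' censored below the per-reaction floor. Every target gets a seven-point
#' ten-fold standard series (10^1..10^7 copies/reaction) with the same
#' noise model. All randomness is governed by `truth$seed`.
#'
#' @param truth an `rdh_synth_truth`.
#' @return list with `plate` (reaction data frame), `meta`, and `truth`.
#' @export
simulate_plate <- function(truth) {
  stopifnot(inherits(truth, "rdh_synth_truth"))
  set.seed(truth$seed)
  panel <- names(truth$strains[[1]]$gene_content)
  targets <- c("Dhc16S", panel)
  ratios <- true_ratio_matrix(truth)
  samples <- rownames(truth$abundance_series)
  curve <- list(slope = truth$slope, intercept = truth$intercept)

  rows <- list()
  widx <- 0L
  emit <- function(target, cq, dil, is_std, std_copies, sid) {
    widx <<- widx + 1L
    rows[[widx]] <<- data.frame(
      well = sprintf("W%03d", widx), sample_id = sid, target = target,
      cq = cq, dilution_factor = dil, is_standard = is_std,
      standard_copies = std_copies, stringsAsFactors = FALSE)
  }
  noisy_cq <- function(copies) {
    forward_cq(copies, curve) + stats::rnorm(1, 0, truth$cq_noise_sd)
  }

  for (tg in targets) {
    for (copies in 10^(1:7)) {
      emit(tg, noisy_cq(copies), 1, TRUE, copies, NA_character_)
    }
  }
  for (sid in samples) {
    mrow <- truth$meta[truth$meta$sample_id == sid, , drop = FALSE]
    for (tg in targets) {
      per_unit <- if (tg == "Dhc16S") truth$total_16s_per_unit else
        truth$total_16s_per_unit * ratios[tg, sid]
      copies_rxn <- per_unit * mrow$volume_filtered *
        mrow$template_volume_ul / mrow$elution_volume_ul
      for (dil in c(1, 10)) {
        eff <- copies_rxn / dil
        for (rep in 1:2) {
          cq <- if (eff < truth$floor_copies_rxn) NA_real_ else noisy_cq(eff)
          emit(tg, cq, dil, FALSE, NA_real_, sid)
        }
      }
    }
  }
  plate <- do.call(rbind, rows)
  list(plate = plate, meta = truth$meta, truth = truth)
}

#' Write a simulated plate to disk
#'
#' @param sim result of [simulate_plate()].
#' @param dir output directory; writes `plate.csv`, `meta.csv`,
#'   `truth.json`.
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  plate <- sim$plate
  plate$cq <- ifelse(is.na(plate$cq), "no-amplification",
                     format(plate$cq, digits = 10))
  write.table(plate, file.path(dir, "plate.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  write.table(sim$meta, file.path(dir, "meta.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  tr <- sim$truth
  jsonlite::write_json(list(
    strains = lapply(tr$strains, function(s)
      list(strain_id = s$strain_id, gene_content = as.list(s$gene_content),
           fitness = as.list(s$fitness))),
    abundance_series = apply(tr$abundance_series, 1, as.list),
    total_16s_per_unit = tr$total_16s_per_unit,
    slope = tr$slope, intercept = tr$intercept,
    cq_noise_sd = tr$cq_noise_sd, seed = tr$seed,
    floor_copies_rxn = tr$floor_copies_rxn),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(dir)
}

#' A 12-sample, 4-acceptor demonstration community
#'
#' Four electron-acceptor groups (TCE, cDCE, VC, 1,2-DCA) of three samples
#' each. Eight strains (two preferring each acceptor) are enriched from a
#' common inoculum by 8 transfers on their group's acceptor; within-group
#' samples differ by small Dirichlet-like jitter of the final abundances.
#' Mirrors the structure in which fingerprints cluster by acceptor.
#'
#' @param seed integer seed.
#' @param cq_noise_sd Cq noise (default 0.15).
#' @return an `rdh_synth_truth` whose `meta` carries an `acceptor` column.
#' @export
demo_truth <- function(seed = 1, cq_noise_sd = 0.15) {
  acceptors <- c("TCE", "cDCE", "VC", "DCA")
  strains <- make_strains(8, overlap = 0.25, seed = seed,
                          acceptors = acceptors,
                          fit_preferred = 2, fit_other = 0.5)
  set.seed(seed + 1L)
  ab <- matrix(0, 12, 8)
  sample_ids <- character(12)
  acc_of_sample <- character(12)
  row <- 0L
  for (acc in acceptors) {
    final <- simulate_selection(strains, rep(acc, 8))
    base <- final[nrow(final), ]
    for (repi in 1:3) {
      row <- row + 1L
      jit <- base * exp(stats::rnorm(8, 0, 0.15))
      ab[row, ] <- jit / sum(jit)
      sample_ids[row] <- paste0(acc, "_", repi)
      acc_of_sample[row] <- acc
    }
  }
  rownames(ab) <- sample_ids
  meta <- sample_meta(sample_ids, volume_filtered = 10)
  meta$acceptor <- acc_of_sample
  synthetic_truth(strains, ab, cq_noise_sd = cq_noise_sd, seed = seed,
                  meta = meta)
}

#' Run the full pipeline on a simulated plate
#'
#' simulate -> fit curves & quantify -> ratio profiles.
#'
#' @param truth an `rdh_synth_truth`.
#' @return list with `profiles`, `measurements`, `curves`, `truth`.
#' @export
run_pipeline <- function(truth) {
  sim <- simulate_plate(truth)
  q <- quantify_plate(sim$plate, sim$meta,
                      lowest_quantifiable_copies_rxn = truth$floor_copies_rxn)
  profiles <- lapply(split(q$measurements, q$measurements$sample_id),
                     compute_ratios)
  # keep simulation sample order
  profiles <- profiles[rownames(truth$abundance_series)]
  list(profiles = profiles, measurements = q$measurements,
       curves = q$curves, truth = truth)
}
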