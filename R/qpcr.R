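# qPCR absolute quantification: standard curves, Cq -> copies, replicate
# merging, concentration scaling and method detection limits.
#
# The calibration model is Cq = intercept + slope * log10(copies); the
# amplification efficiency is E = 10^(-1/slope) - 1 (100 % at slope
# -1/log10(2) ~ -3.3219). "No amplification" is a censored observation,
# never zero. Replicates are combined by geometric mean (Cq is log-domain);
# when the undiluted and ten-fold-diluted estimates disagree by more than
# `agreement_fold`, the diluted estimate wins (matrix-inhibition
# assumption) and the result is flagged.

#' Construct a qPCR reaction table
#'
#' @param well well label.
#' @param target target gene name.
#' @param cq quantification cycle; `NA` means no amplification.
#' @param dilution_factor template dilution (1 = undiluted, 10 = ten-fold).
#' @param is_standard logical, calibrator well?
#' @param standard_copies known copies/reaction for standards.
#' @param sample_id sample the well belongs to (empty for standards).
#' @return a data frame of reactions.
#' @export
reactions <- function(well, target, cq, dilution_factor = 1,
                      is_standard = FALSE, standard_copies = NA_real_,
                      sample_id = NA_character_) {
  df <- data.frame(well = well, target = target, cq = as.numeric(cq),
                   dilution_factor = dilution_factor,
                   is_standard = is_standard,
                   standard_copies = standard_copies,
                   sample_id = sample_id, stringsAsFactors = FALSE)
  if (any(df$dilution_factor < 1)) stop("dilution_factor must be >= 1")
  if (any(df$is_standard & !is.finite(df$standard_copies))) {
    stop("standards need known copies")
  }
  if (any(is.finite(df$cq) & df$cq <= 0)) stop("numeric Cq must be > 0")
  df
}

#' Sample processing metadata
#'
#' @param sample_id sample name.
#' @param volume_filtered volume of culture (mL) or groundwater (L)
#'   filtered, in the unit implied by `matrix`.
#' @param elution_volume_ul DNA elution volume in microlitres.
#' @param template_volume_ul template volume per reaction in microlitres
#'   (default 2).
#' @param matrix `"culture_per_mL"` or `"groundwater_per_L"`.
#' @return a data frame of sample metadata.
#' @export
sample_meta <- function(sample_id, volume_filtered, elution_volume_ul = 50,
                        template_volume_ul = 2,
                        matrix = "culture_per_mL") {
  if (!all(matrix %in% c("culture_per_mL", "groundwater_per_L"))) {
    stop("unknown matrix unit")
  }
  df <- data.frame(sample_id = sample_id, volume_filtered = volume_filtered,
                   elution_volume_ul = elution_volume_ul,
                   template_volume_ul = template_volume_ul,
                   matrix = matrix, stringsAsFactors = FALSE)
  if (any(df$volume_filtered <= 0 | df$elution_volume_ul <= 0 |
            df$template_volume_ul <= 0)) stop("volumes must be positive")
  df
}

#' Fit a log-linear standard curve
#'
#' Ordinary least squares of Cq on log10(copies/reaction).
#'
#' @param standards reaction data frame rows with `is_standard = TRUE`,
#'   numeric `cq` and `standard_copies`; at least 3 distinct
#'   concentrations.
#' @param target optional target name recorded on the curve.
#' @return an object of class `rdh_standard_curve` with `slope`,
#'   `intercept`, `r2`, `efficiency`, `quant_range`.
#' @export
fit_standard_curve <- function(standards, target = NULL) {
  st <- standards[is.finite(standards$cq) & is.finite(standards$standard_copies), ,
                  drop = FALSE]
  if (length(unique(st$standard_copies)) < 3) {
    stop("need at least 3 distinct standard concentrations with numeric Cq")
  }
  lx <- log10(st$standard_copies)
  fit <- lm(st$cq ~ lx)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) stop("positive standard-curve slope: calibrator order suspect")
  # suppress lm's "essentially perfect fit" chatter on noiseless calibrators
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(
    target = if (is.null(target)) unique(st$target)[1] else target,
    slope = slope,
    intercept = unname(coef(fit)[1]),
    r2 = r2,
    efficiency = 10^(-1 / slope) - 1,
    quant_range = range(st$standard_copies)
  ), class = "rdh_standard_curve")
}

#' @export
print.rdh_standard_curve <- function(x, ...) {
  cat(sprintf(
    "Standard curve [%s]: slope %.4f, intercept %.2f, R2 %.4f, eff %.1f%%, range %.3g-%.3g copies/rxn\n",
    x$target, x$slope, x$intercept, x$r2, 100 * x$efficiency,
    x$quant_range[1], x$quant_range[2]))
  invisible(x)
}

#' Expected Cq for a copy number under a standard curve
#'
#' @param copies copies/reaction.
#' @param curve an `rdh_standard_curve` (or list with slope/intercept).
#' @return Cq values.
#' @export
forward_cq <- function(copies, curve) {
  curve$intercept + curve$slope * log10(copies)
}

#' Convert a Cq to absolute copies per reaction
#'
#' `copies = dilution_factor * 10^((cq - intercept)/slope)`. A
#' non-amplifying reaction (`cq = NA`) returns a censored marker.
#'
#' @param cq quantification cycle (`NA` = no amplification).
#' @param curve an `rdh_standard_curve`.
#' @param dilution_factor template dilution factor.
#' @return list with `copies`, `censored`, and `flags`
#'   (`above_range`/`below_range` when the per-reaction estimate leaves
#'   the calibrated range).
#' @export
quantify_reaction <- function(cq, curve, dilution_factor = 1) {
  if (!is.finite(cq)) {
    return(list(copies = NA_real_, censored = TRUE, flags = character(0)))
  }
  raw <- 10^((cq - curve$intercept) / curve$slope)
  flags <- character(0)
  if (raw > curve$quant_range[2]) flags <- "above_range"
  if (raw < curve$quant_range[1]) flags <- "below_range"
  list(copies = dilution_factor * raw, censored = FALSE, flags = flags)
}

#' Merge replicate reactions into one per-sample estimate
#'
#' Dilution-corrected estimates are combined by geometric mean. If the
#' undiluted and diluted estimates differ by more than `agreement_fold`,
#' the diluted estimate is kept (inhibition assumption) and
#' `dilution_disagreement` is flagged.
#'
#' @param rx reaction rows for one sample/target.
#' @param curve the target's `rdh_standard_curve`.
#' @param agreement_fold maximum accepted fold-difference between dilution
#'   levels (default 2).
#' @return list with `copies_rxn` (undiluted-equivalent copies/reaction),
#'   `censored`, `qc_flags`.
#' @export
merge_replicates <- function(rx, curve, agreement_fold = 2) {
  if (nrow(rx) == 0) stop("no reactions to merge")
  qs <- lapply(seq_len(nrow(rx)), function(i) {
    quantify_reaction(rx$cq[i], curve, rx$dilution_factor[i])
  })
  ok <- !vapply(qs, `[[`, logical(1), "censored")
  if (!any(ok)) {
    return(list(copies_rxn = NA_real_, censored = TRUE, qc_flags = character(0)))
  }
  est <- vapply(qs[ok], `[[`, numeric(1), "copies")
  dil <- rx$dilution_factor[ok]
  flags <- unique(unlist(lapply(qs[ok], `[[`, "flags")))
  und <- est[dil == 1]; di <- est[dil > 1]
  if (length(und) && length(di)) {
    g_und <- geomean(und); g_di <- geomean(di)
    fold <- max(g_und, g_di) / min(g_und, g_di)
    if (fold > agreement_fold) {
      return(list(copies_rxn = g_di, censored = FALSE,
                  qc_flags = union(flags, "dilution_disagreement")))
    }
  }
  list(copies_rxn = geomean(est), censored = FALSE, qc_flags = flags)
}

#' Scale copies per reaction to copies per sample unit
#'
#' `copies_per_unit = copies_rxn * (elution_volume / template_volume) /
#' volume_filtered`, per mL of culture or per L of groundwater according
#' to the sample's matrix.
#'
#' @param copies_rxn copies per reaction.
#' @param meta one row of [sample_meta()].
#' @return copies per mL or per L.
#' @export
to_concentration <- function(copies_rxn, meta) {
  stopifnot(nrow(meta) == 1)
  copies_rxn * (meta$elution_volume_ul / meta$template_volume_ul) /
    meta$volume_filtered
}

#' Method detection limit for a sample
#'
#' The per-reaction quantification floor (default 10 copies/reaction, the
#' lowest calibrator routinely quantifiable) scaled by the sample's
#' elution, template and filtered volumes.
#'
#' @param meta one row of [sample_meta()].
#' @param lowest_quantifiable_copies_rxn per-reaction floor.
#' @return MDL in copies per mL or per L.
#' @export
compute_mdl <- function(meta, lowest_quantifiable_copies_rxn = 10) {
  to_concentration(lowest_quantifiable_copies_rxn, meta)
}

#' Quantify a whole plate
#'
#' Fits one standard curve per target from calibrator wells, merges sample
#' replicates, converts to concentrations and applies the MDL: estimates
#' below the MDL (or non-amplifying) are censored.
#'
#' @param plate reaction data frame (see [reactions()]; standards carry
#'   `is_standard = TRUE`, unknowns a `sample_id`).
#' @param meta [sample_meta()] data frame covering every sample.
#' @param agreement_fold see [merge_replicates()].
#' @param lowest_quantifiable_copies_rxn per-reaction floor for the MDL.
#' @return list with `measurements` (data frame: `sample_id`, `target`,
#'   `copies_per_unit`, `unit`, `censored`, `mdl_per_unit`, `qc_flags`)
#'   and `curves` (per-target `rdh_standard_curve`s).
#' @export
quantify_plate <- function(plate, meta, agreement_fold = 2,
                           lowest_quantifiable_copies_rxn = 10) {
  targets <- unique(plate$target)
  curves <- lapply(setNames(targets, targets), function(tg) {
    fit_standard_curve(plate[plate$is_standard & plate$target == tg, ,
                             drop = FALSE], target = tg)
  })
  unk <- plate[!plate$is_standard, , drop = FALSE]
  if (any(is.na(unk$sample_id))) stop("unknown wells must carry a sample_id")
  rows <- list()
  for (sid in unique(unk$sample_id)) {
    mrow <- meta[meta$sample_id == sid, , drop = FALSE]
    if (nrow(mrow) != 1) stop("metadata missing (or duplicated) for sample ", sid)
    unit <- if (mrow$matrix == "culture_per_mL") "copies/mL" else "copies/L"
    mdl <- compute_mdl(mrow, lowest_quantifiable_copies_rxn)
    for (tg in unique(unk$target[unk$sample_id == sid])) {
      rx <- unk[unk$sample_id == sid & unk$target == tg, , drop = FALSE]
      mg <- merge_replicates(rx, curves[[tg]], agreement_fold)
      if (mg$censored) {
        conc <- NA_real_; cens <- TRUE
      } else {
        conc <- to_concentration(mg$copies_rxn, mrow)
        cens <- conc < mdl
        if (cens) conc <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, target = tg, copies_per_unit = conc, unit = unit,
        censored = cens, mdl_per_unit = mdl,
        qc_flags = join_flags(mg$qc_flags), stringsAsFactors = FALSE)
    }
  }
  list(measurements = do.call(rbind, rows), curves = curves)
}

#' Read a plate CSV
#'
#' Columns: `well`, `sample_id`, `target`, `cq` (empty or `NA` for no
#' amplification), `dilution_factor`, `is_standard`, `standard_copies`.
#'
#' @param path CSV file path.
#' @return reaction data frame.
#' @export
read_plate <- function(path) {
  tab <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE,
                    na.strings = c("NA", "", "no-amplification"))
  reactions(tab$well, tab$target, tab$cq, tab$dilution_factor,
            as.logical(tab$is_standard), tab$standard_copies, tab$sample_id)
}

#' Read a sample metadata CSV
#'
#' @param path CSV with [sample_meta()] columns.
#' @return metadata data frame.
#' @export
read_sample_meta <- function(path) {
  tab <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  sample_meta(tab$sample_id, tab$volume_filtered, tab$elution_volume_ul,
              tab$template_volume_ul, tab$matrix)
}
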