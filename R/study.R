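#' Run the full phantom study end to end
#'
#' Simulates a grouped phantom cohort, estimates each subject's
#' normalization from the T1, runs both automatic segmentation pipelines
#' (RATSI and RSIAT), quantifies regional SUVs, evaluates both methods
#' against the ground-truth labels (the phantom's stand-in for manual
#' segmentation) in common MNI space, and computes the group statistics:
#' paired t on Dice/Hausdorff between methods, one-way ANOVA on SUVs
#' across methods, Bland-Altman agreement of automatic versus
#' ground-truth SUV_mean, and the PD-vs-MSA regional comparison
#' (variance F-test then two-sample t).
#'
#' @param out_dir Output directory for the report tables (TSV) and the
#'   provenance JSON; `NULL` returns results without writing.
#' @param n_pd,n_msa Group sizes.
#' @param spec A [phantom_spec()]; its seed drives every random draw.
#' @param reg_params A [registration_params()].
#' @param eval_labels Integer labels evaluated for Dice/HD (default the
#'   four caudate/putamen nuclei).
#' @param quant_labels Labels quantified for SUV comparisons (default
#'   the six named nuclei).
#' @param verbose Log progress to the console.
#' @return A list of data.frames: `agreement` (per subject x method x
#'   region DC/HD), `agreement_summary`, `method_tests` (paired t on
#'   DC/HD; per-region SUV ANOVA), `quant` (per subject x method x
#'   region SUVs), `bland_altman`, `group_comparison` (PD vs MSA via
#'   RATSI), and `manifest`.
#' @export
run_study <- function(out_dir = NULL, n_pd = 20L, n_msa = 8L,
                      spec = phantom_spec(), reg_params = registration_params(),
                      eval_labels = NUCLEUS_LABELS[1:4],
                      quant_labels = NUCLEUS_LABELS, verbose = FALSE) {
  op <- options(neuroquant.verbose = verbose); on.exit(options(op))
  profile <- group_uptake_profile(spec$n_regions)
  atlas <- make_atlas_phantom(spec)
  cohort <- make_cohort(atlas, profile, n_pd, n_msa, spec)
  eval_names <- names(eval_labels) %||% as.character(eval_labels)
  quant_names <- names(quant_labels) %||% as.character(quant_labels)

  agreement <- list(); quant <- list()
  for (s in cohort$subjects) {
    nq_log("registering ", s$id)
    norm <- estimate_normalization(s$t1, atlas$reference_t1, reg_params)
    ratsi <- ratsi_segment(atlas, norm)
    rsiat <- rsiat_segment(atlas, norm, s$pet)
    manual <- segmentation_result(s$truth_labels, method = "manual")

    suv_subj <- suv_image(s$pet, s$suv_inputs)
    suv_mni <- suv_image(rsiat$normalized_pet, s$suv_inputs)

    for (m in c("manual", "RATSI", "RSIAT")) {
      q <- switch(m,
        manual = regional_quantify(suv_subj, manual, quant_labels,
                                   quant_names),
        RATSI = regional_quantify(suv_subj, ratsi, quant_labels,
                                  quant_names),
        RSIAT = regional_quantify(suv_mni, rsiat$segmentation,
                                  quant_labels, quant_names))
      q$subject <- s$id; q$group <- s$group; q$method <- m
      quant[[length(quant) + 1L]] <- q
    }
    for (m in c("RATSI", "RSIAT")) {
      seg <- if (m == "RATSI") ratsi else rsiat$segmentation
      ev <- evaluate_vs_truth(seg, s$truth_labels, norm, eval_labels,
                              eval_names)
      ev$subject <- s$id; ev$group <- s$group; ev$method <- m
      agreement[[length(agreement) + 1L]] <- ev
    }
  }
  agreement <- do.call(rbind, agreement)
  quant <- do.call(rbind, quant)
  quant$method <- factor(quant$method, levels = c("manual", "RSIAT",
                                                  "RATSI"))

  agg <- stats::aggregate(cbind(dice, hausdorff_mm) ~ method + name,
                          data = agreement, FUN = mean)
  sdv <- stats::aggregate(cbind(dice, hausdorff_mm) ~ method + name,
                          data = agreement, FUN = stats::sd)
  names(sdv)[3:4] <- c("dice_sd", "hd_sd")
  agreement_summary <- merge(agg, sdv)

  # Paired t between methods on DC and HD (per region, PD-group style
  # pairing by subject).
  method_tests <- list()
  for (rn in unique(agreement$name)) {
    sub <- agreement[agreement$name == rn & !is.na(agreement$dice), ]
    wide_d <- stats::reshape(sub[, c("subject", "method", "dice")],
                             idvar = "subject", timevar = "method",
                             direction = "wide")
    wide_h <- stats::reshape(sub[, c("subject", "method", "hausdorff_mm")],
                             idvar = "subject", timevar = "method",
                             direction = "wide")
    if (nrow(wide_d) >= 2L) {
      td <- paired_t(wide_d$dice.RATSI, wide_d$dice.RSIAT)
      th <- paired_t(wide_h$hausdorff_mm.RATSI,
                     wide_h$hausdorff_mm.RSIAT)
      method_tests[[length(method_tests) + 1L]] <-
        data.frame(name = rn, metric = c("dice", "hausdorff"),
                   statistic = c(td$statistic, th$statistic),
                   p_value = c(td$p_value, th$p_value),
                   decision = c(td$decision, th$decision))
    }
  }
  # ANOVA across the three methods on SUV_mean and SUV_max per region.
  for (rn in unique(quant$name)) {
    sub <- quant[quant$name == rn, ]
    for (metric in c("suv_mean", "suv_max")) {
      gr <- split(sub[[metric]], sub$method)
      an <- one_way_anova(gr)
      method_tests[[length(method_tests) + 1L]] <-
        data.frame(name = rn, metric = paste0("anova_", metric),
                   statistic = an$statistic, p_value = an$p_value,
                   decision = an$decision)
    }
  }
  method_tests <- do.call(rbind, method_tests)

  # Bland-Altman: automatic vs ground-truth SUV_mean pooled over the
  # evaluated regions.
  ba <- list()
  for (m in c("RSIAT", "RATSI")) {
    man <- quant[quant$method == "manual", ]
    aut <- quant[quant$method == m, ]
    key <- paste(man$subject, man$label)
    aut <- aut[match(key, paste(aut$subject, aut$label)), ]
    res <- bland_altman(man$suv_mean, aut$suv_mean)
    ba[[m]] <- data.frame(method = m, bias = res$bias,
                          loa_low = res$loa_low, loa_high = res$loa_high,
                          fraction_within = res$fraction_within,
                          pairs = res$pairs)
  }
  ba <- do.call(rbind, ba)

  group_comparison <- NULL
  if (n_pd >= 2L && n_msa >= 2L) {
    ratsi_q <- quant[quant$method == "RATSI", ]
    group_comparison <- compare_groups_by_region(ratsi_q, "PD", "MSA")
  }

  report <- list(agreement = agreement,
                 agreement_summary = agreement_summary,
                 method_tests = method_tests, quant = quant,
                 bland_altman = ba, group_comparison = group_comparison,
                 manifest = cohort$manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, f) if (!is.null(df))
      utils::write.table(df, file.path(out_dir, f), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    wt(agreement, "agreement.tsv")
    wt(agreement_summary, "agreement_summary.tsv")
    wt(method_tests, "method_tests.tsv")
    wt(quant, "quantification.tsv")
    wt(ba, "bland_altman.tsv")
    wt(group_comparison, "group_comparison.tsv")
    wt(cohort$manifest, "manifest.tsv")
    jsonlite::write_json(
      list(package = "neuroquant",
           version = as.character(utils::packageVersion("neuroquant")),
           seed = spec$seed, n_pd = n_pd, n_msa = n_msa,
           grid_shape = spec$grid_shape, spacing = spec$spacing,
           deform_amplitude = spec$deform_amplitude,
           noise_sd = spec$noise_sd, psf_fwhm = spec$psf_fwhm,
           atrophy = as.list(spec$atrophy %||% list()),
           timestamp = format(Sys.time(), tz = "UTC")),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE)
  }
  report
}
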