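#' Configuration for the paired-expression simulator
#'
#' Describes a synthetic study of paired tumor/normal arrays in the shape the
#' analysis consumes: log-normal baseline intensities, an additive
#' log-scale tumor effect per pathway class, detection calls tied to signal
#' level, and one to three probe sets per gene with a planted best probe.
#'
#' The default effect profile encodes the qualitative direction pattern of a
#' clear-cell renal carcinoma Warburg shift: glycolysis up, gluconeogenesis
#' strongly down, serine/glycine down, TCA mildly down, pentose phosphate
#' pathway null. Means and spreads are on the natural-log fold-change scale.
#'
#' @param n_patients number of tumor/normal pairs (default 10).
#' @param genes data frame with columns `gene` and `pathway`; default: the
#'   gene nodes of the packaged network with their first pathway tag.
#' @param effect_profile named list `pathway -> c(mean_lnfc, sd_lnfc)`;
#'   pathways not listed get `c(0, 0.3)`.
#' @param baseline_log_intensity `c(mean, sd)` of the per-gene natural-log
#'   baseline intensity, shared across patients so that samples resemble one
#'   another the way arrays of one tissue do (default `c(log(500), 1.2)`).
#' @param patient_baseline_sd log-scale spread of a patient's normal-tissue
#'   deviation from the gene baseline (default 0.3).
#' @param measurement_noise_sd extra log-scale noise on the tumor signal
#'   (default 0.35).
#' @param absent_threshold intensity below which a call is Absent (default 50).
#' @param marginal_band upper edge of the Marginal band: signals in
#'   `[absent_threshold, marginal_band)` are called Marginal (default 80).
#' @param random_absent_rate probability of a sporadic Absent call regardless
#'   of signal (default 0.01), so call filtering is exercised sporadically as
#'   well as systematically.
#' @param probes_per_gene_prob probabilities of a gene having 1, 2 or 3 probe
#'   sets (default `c(0.5, 0.3, 0.2)`).
#' @param attenuation signal multipliers of the 2nd (`_s_at`) and 3rd
#'   (`_x_at`) probe set relative to the planted `_at` probe
#'   (default `c(0.3, 0.1)`).
#' @param all_absent_genes genes forced to sub-threshold signal in both
#'   tissues, so both calls are Absent for every patient.
#' @return object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(n_patients = 10,
                              genes = NULL,
                              effect_profile = list(
                                glycolysis = c(log(3), 0.45),
                                gluconeogenesis = c(-log(8), 0.6),
                                serine_glycine = c(-log(4), 0.6),
                                tca = c(-log(1.6), 0.35),
                                ppp = c(0, 0.3),
                                transporters = c(log(2), 0.5),
                                fructose = c(-log(2), 0.4),
                                glutaminolysis = c(-log(2), 0.4),
                                pyruvate_metabolism = c(0, 0.5),
                                fatty_acid_synthesis = c(0, 0.4),
                                pkm_splicing = c(0, 0.3)),
                              baseline_log_intensity = c(log(500), 1.2),
                              patient_baseline_sd = 0.3,
                              measurement_noise_sd = 0.35,
                              absent_threshold = 50,
                              marginal_band = 80,
                              random_absent_rate = 0.01,
                              probes_per_gene_prob = c(0.5, 0.3, 0.2),
                              attenuation = c(0.3, 0.1),
                              all_absent_genes = character()) {
  if (is.null(genes)) {
    net <- load_network()
    gn <- net$nodes[net$nodes$kind == "gene", ]
    genes <- data.frame(gene = gn$id,
                        pathway = vapply(strsplit(gn$pathways, "|", fixed = TRUE),
                                         `[`, character(1), 1),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(genes), all(c("gene", "pathway") %in% names(genes)))
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (baseline_log_intensity[2] < 0 || measurement_noise_sd < 0 ||
      patient_baseline_sd < 0)
    stop("spreads must be non-negative")
  if (absent_threshold <= 0) stop("absent_threshold must be positive")
  if (marginal_band < absent_threshold)
    stop("marginal_band must not be below absent_threshold")
  bad_sd <- vapply(effect_profile, function(e) e[2] < 0, logical(1))
  if (any(bad_sd)) stop("effect-profile sds must be >= 0")
  p <- probes_per_gene_prob / sum(probes_per_gene_prob)
  if (length(p) != 3) stop("probes_per_gene_prob must have 3 entries")
  structure(list(n_patients = n_patients, genes = genes,
                 effect_profile = effect_profile,
                 baseline_log_intensity = baseline_log_intensity,
                 patient_baseline_sd = patient_baseline_sd,
                 measurement_noise_sd = measurement_noise_sd,
                 absent_threshold = absent_threshold,
                 marginal_band = marginal_band,
                 random_absent_rate = random_absent_rate,
                 probes_per_gene_prob = p,
                 attenuation = attenuation,
                 all_absent_genes = all_absent_genes),
            class = "sim_config")
}

#' Simulate a paired tumor/normal expression study
#'
#' Generates an expression table with detection calls, a patient pairing, a
#' probe annotation and the ground truth used to generate them. Normal-tissue
#' signals are log-normal; tumor signals multiply the normal signal by
#' `exp(realized ln-FC + noise)` where the realized per-patient ln-FC is
#' drawn around the gene's true (pathway-level) ln-FC. Calls are `A` below
#' the absent threshold, `M` in the marginal band, `P` above, with a small
#' sporadic Absent rate on top. Genes with several probe sets get attenuated
#' `_s_at` / `_x_at` duplicates; the full-signal `_at` probe is the planted
#' best probe. Fully reproducible given `seed`.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return list with elements `table` ([expression_table()]), `pairing`
#'   ([sample_pairing()]), `annotation` (probe-to-gene data frame) and
#'   `truth` (list: `true_ln_fc`, `realized_ln_fc` patients x genes matrix,
#'   `best_probe`, `config`).
#' @export
simulate_expression <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  genes <- config$genes$gene
  ng <- length(genes)
  np <- config$n_patients
  pathway <- setNames(config$genes$pathway, genes)
  prof <- function(pw) {
    e <- config$effect_profile[[pw]]
    if (is.null(e)) c(0, 0.3) else e
  }
  true_ln <- vapply(genes, function(g) prof(pathway[g])[1], numeric(1))
  sd_ln <- vapply(genes, function(g) prof(pathway[g])[2], numeric(1))
  patients <- sprintf("pat%02d", seq_len(np))
  tumor_ids <- paste0(patients, "_T")
  normal_ids <- paste0(patients, "_N")
  base <- config$baseline_log_intensity
  gene_base <- stats::rnorm(ng, base[1], base[2])
  low <- genes %in% config$all_absent_genes
  gene_base[low] <- log(config$absent_threshold / 4)
  normal_ln <- matrix(rep(gene_base, each = np) +
                        stats::rnorm(np * ng, 0, config$patient_baseline_sd),
                      nrow = np, dimnames = list(patients, genes))
  realized <- matrix(stats::rnorm(np * ng, rep(true_ln, each = np),
                                  rep(sd_ln, each = np)), nrow = np,
                     dimnames = list(patients, genes))
  noise <- matrix(stats::rnorm(np * ng, 0, config$measurement_noise_sd),
                  nrow = np)
  normal_sig <- exp(normal_ln)
  tumor_sig <- normal_sig * exp(realized + noise)
  if (any(low)) tumor_sig[, low] <- exp(normal_ln[, low])  # stays sub-threshold
  n_probes <- sample(1:3, ng, replace = TRUE, prob = config$probes_per_gene_prob)
  suffixes <- c("_at", "_s_at", "_x_at")
  att <- c(1, config$attenuation)
  probe_rows <- list()
  ann_rows <- list()
  best_probe <- character(ng)
  names(best_probe) <- genes
  for (i in seq_len(ng)) {
    g <- genes[i]
    for (k in seq_len(n_probes[i])) {
      pid <- sprintf("2%05d%s", i * 10 + k, suffixes[k])
      if (k == 1) best_probe[g] <- pid
      probe_rows[[pid]] <- c(tumor_sig[, i], normal_sig[, i]) * att[k]
      ann_rows[[pid]] <- g
    }
  }
  sig <- do.call(rbind, probe_rows)
  colnames(sig) <- c(tumor_ids, normal_ids)
  calls <- matrix(ifelse(sig < config$absent_threshold, "A",
                  ifelse(sig < config$marginal_band, "M", "P")),
                  nrow = nrow(sig), dimnames = dimnames(sig))
  sporadic <- matrix(stats::runif(length(sig)) < config$random_absent_rate,
                     nrow = nrow(sig))
  calls[sporadic] <- "A"
  table <- expression_table(sig, calls)
  pairing <- sample_pairing(data.frame(patient = patients, tumor = tumor_ids,
                                       normal = normal_ids,
                                       stringsAsFactors = FALSE))
  annotation <- data.frame(probe_id = names(ann_rows),
                           gene_symbol = unlist(ann_rows),
                           stringsAsFactors = FALSE)
  annotation$suffix_class <- probe_suffix_class(annotation$probe_id)
  rownames(annotation) <- NULL
  truth <- list(true_ln_fc = true_ln,
                realized_ln_fc = realized,
                best_probe = best_probe,
                pathway = pathway,
                config = config)
  list(table = table, pairing = pairing, annotation = annotation,
       truth = truth)
}

#' Compare pipeline summaries against simulator ground truth
#'
#' Reports, per pathway class, the bias and root-mean-square error of the
#' estimated log average fold change against the true ln-FC, and a confusion
#' matrix of the DE classification against the truth (`|true FC| > threshold`
#' with matching sign).
#'
#' @param truth the `truth` element of [simulate_expression()].
#' @param summaries per-gene summary data frame (e.g. `fit$summary`).
#' @param fc_threshold DE magnitude threshold used for the truth classes.
#' @return list with `per_pathway` (data frame: pathway, n, bias, rmse) and
#'   `confusion` (table of true vs estimated class).
#' @export
truth_comparison <- function(truth, summaries, fc_threshold = 2) {
  if (!all(summaries$gene %in% names(truth$true_ln_fc)))
    stop("summaries contain gene(s) unknown to the simulation truth")
  tl <- truth$true_ln_fc[summaries$gene]
  pw <- truth$pathway[summaries$gene]
  est_ln <- sign(summaries$avg_fc) * log(abs(summaries$avg_fc))
  err <- est_ln - tl
  per <- do.call(rbind, lapply(split(seq_along(err), pw), function(idx)
    data.frame(pathway = pw[idx[1]], n = length(idx),
               bias = mean(err[idx]), rmse = sqrt(mean(err[idx]^2)),
               stringsAsFactors = FALSE)))
  rownames(per) <- NULL
  truth_class <- ifelse(tl > log(fc_threshold), "over",
                 ifelse(tl < -log(fc_threshold), "under", "unchanged"))
  lv <- c("over", "under", "unchanged")
  confusion <- table(truth = factor(truth_class, lv),
                     estimated = factor(summaries$de_class, lv))
  list(per_pathway = per, confusion = confusion)
}
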