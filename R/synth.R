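#' Synthetic study scenario
#'
#' Defines the conditions of the synthetic manipulation experiment and field
#' survey that the generators emulate: a 40 cm sand column, DIC and sulfate
#' porewater profiles in defaunated vs refaunated plots sampled at 2 cm
#' intervals over the top 30 cm, four sampling dates (days 4, 18, 26 and 37
#' after sieving/homogenization, with porewater calibration restricted to
#' the first two), physical exchange concentrated in the top ~10 cm,
#' bioirrigation over ~10-20 cm, biological particle mixing over the
#' 12.5-25 cm feeding layer, and a grain-size coarsening bump at 15-25 cm.
#' Noise is multiplicative log-normal for concentrations (5% by default)
#' and additive Gaussian for sand fractions.
#'
#' @param seed master seed; every generator output is a pure function of
#'   (config, seed).
#' @param grid sediment grid.
#' @param mixing true porewater mixing parameters `a_P` (1/day), `L_P` (cm),
#'   `a_B` (1/day), `z1`, `z2` (cm), `ramp` (cm).
#' @param particle true particle mixing parameters `d_P`, `L_DP`, `d_B`,
#'   `w1`, `w2` (cm^2/day and cm).
#' @param solutes per-analyte list of `d0`, `c_ow`, `c_init`, `noise_sdlog`.
#' @param pigments tracer constants `k_chl`, `k_pheo` (1/day), `yield`,
#'   `flux`, `noise_sdlog`.
#' @param times named days since start for time points T1-T4.
#' @param porewater_depths,sediment_depths observation depths (cm).
#' @param sand base sand fraction, feeding bump height, bump window (cm) and
#'   additive noise sd.
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(seed = 1,
                            grid = build_grid(40, 80, 0.4),
                            mixing = list(a_P = 0.4, L_P = 4, a_B = 0.25,
                                          z1 = 10, z2 = 20, ramp = 2),
                            particle = list(d_P = 0.8, L_DP = 4, d_B = 0.15,
                                            w1 = 12.5, w2 = 25),
                            solutes = list(
                              DIC = list(d0 = 0.8, c_ow = 2.1, c_init = 7,
                                         noise_sdlog = 0.05),
                              SO4 = list(d0 = 0.75, c_ow = 28, c_init = 22,
                                         noise_sdlog = 0.05)),
                            pigments = list(k_chl = 0.02, k_pheo = 0.002,
                                            yield = 1, flux = 1.5,
                                            noise_sdlog = 0.1),
                            times = c(T1 = 4, T2 = 18, T3 = 26, T4 = 37),
                            porewater_depths = seq(1, 29, by = 2),
                            sediment_depths = seq(0.5, 29.5, by = 1),
                            sand = list(base = 0.65, bump = 0.2,
                                        window = c(15, 25), ramp = 2,
                                        noise_sd = 0.02)) {
  validate_grid(grid)
  structure(list(seed = seed, grid = grid, mixing = mixing,
                 particle = particle, solutes = solutes, pigments = pigments,
                 times = times, porewater_depths = porewater_depths,
                 sediment_depths = sediment_depths, sand = sand),
            class = "scenario_config")
}

# inversion_config consistent with a scenario (shared experiment constants)
#' @rdname inversion_config
#' @param scenario a [scenario_config()].
#' @export
inversion_config_from_scenario <- function(scenario, n_starts = 8,
                                           seed = scenario$seed) {
  inversion_config(
    grid = scenario$grid,
    analytes = lapply(scenario$solutes, function(s)
      s[c("d0", "c_ow", "c_init")]),
    pigments = scenario$pigments[c("k_chl", "k_pheo", "yield", "flux")],
    ramp = scenario$mixing$ramp, n_starts = n_starts, seed = seed)
}

#' Generate synthetic porewater geochemistry
#'
#' Runs the nonlocal-exchange forward model for the defaunated treatment
#' (physical exchange only) and the refaunated treatment (physical exchange
#' plus the bioirrigation window), samples the configured depths at T1, T2
#' and T4, and applies seeded multiplicative log-normal noise.  The same
#' noise stream is used for both treatments, so with `a_B = 0` the two
#' treatments are bit-identical.
#'
#' @param config a [scenario_config()].
#' @return List with `observations` (data frame: `analyte`, `treatment`,
#'   `time_point`, `day`, `depth_cm`, `value`, `replicate`) and `truth`
#'   (the mixing parameters and noiseless model values).
#' @export
generate_geochem <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  g <- config$grid
  mx <- config$mixing
  alpha_p <- profile_exponential(g, mx$a_P, mx$L_P)
  alpha_b <- profile_window(g, mx$a_B, mx$z1, mx$z2, ramp = mx$ramp)
  days <- config$times[c("T1", "T2", "T4")]
  depths <- config$porewater_depths
  rows <- list()
  truth_rows <- list()
  for (an in names(config$solutes)) {
    sp <- config$solutes[[an]]
    noise <- if (sp$noise_sdlog > 0)
      with_seed(child_seed(config$seed, match(an, names(config$solutes))),
                matrix(rlnorm(length(depths) * length(days),
                              meanlog = -sp$noise_sdlog^2 / 2,
                              sdlog = sp$noise_sdlog),
                       length(depths), length(days)))
    else matrix(1, length(depths), length(days))
    for (trt in c("defaunated", "refaunated")) {
      ab <- if (trt == "refaunated") alpha_b else rep(0, g$n_cells)
      states <- solve_solute(
        g, transport_params(molecular_diffusivity = sp$d0),
        exchange_field(g, alpha_p, ab),
        solute_state(an, rep(sp$c_init, g$n_cells), sp$c_ow),
        duration = max(days), output_times = days)
      for (j in seq_along(days)) {
        model <- approx(g$cell_centers, states[[j]]$concentration,
                        xout = depths, rule = 2)$y
        rows[[length(rows) + 1]] <- data.frame(
          analyte = an, treatment = trt, time_point = names(days)[j],
          day = unname(days[j]), depth_cm = depths,
          value = model * noise[, j], replicate = "I")
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          analyte = an, treatment = trt, time_point = names(days)[j],
          day = unname(days[j]), depth_cm = depths, value = model)
      }
    }
  }
  list(observations = do.call(rbind, rows),
       truth = list(mixing = mx, noiseless = do.call(rbind, truth_rows)))
}

#' Generate synthetic pigment and grain-size profiles
#'
#' Pigments come from the steady-state tracer model per treatment
#' (nonbioturbated: physical mixing only; bioturbated: physical plus the
#' biological window), sampled with log-normal noise at three dates per
#' treatment.  The control sand fraction is constant plus Gaussian noise;
#' the bioturbated profile adds a positive half-cosine bump over the
#' feeding window, so [feeding_intensity()] recovers the planted window.
#'
#' @param config a [scenario_config()].
#' @return List with `pigments`, `sand` data frames and `truth`.
#' @export
generate_pigments_grainsize <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  g <- config$grid
  pc <- config$particle
  pg <- config$pigments
  depths <- config$sediment_depths
  d_phys <- profile_exponential(g, pc$d_P, pc$L_DP)
  d_bio <- profile_window(g, pc$d_B, pc$w1, pc$w2, ramp = config$mixing$ramp)
  tp <- list(bioturbated = c("T1", "T2", "T4"),
             nonbioturbated = c("T2", "T3", "T4"))
  pig_rows <- list()
  truth_profiles <- list()
  idx <- 10L
  for (trt in names(tp)) {
    db <- if (trt == "bioturbated") d_bio else rep(0, g$n_cells)
    st <- solve_pigments_steady(
      g, transport_params(biodiffusion_physical = d_phys,
                          biodiffusion_biological = db,
                          chl_decay = pg$k_chl, pheo_decay = pg$k_pheo,
                          chl_to_pheo_yield = pg$yield,
                          surface_chl_flux = pg$flux))
    truth_profiles[[trt]] <- st
    for (an in c("chl_a", "pheopigment")) {
      model <- approx(g$cell_centers, st[[an]], xout = depths, rule = 2)$y
      for (t_lab in tp[[trt]]) {
        idx <- idx + 1L
        noise <- if (pg$noise_sdlog > 0)
          with_seed(child_seed(config$seed, idx),
                    rlnorm(length(depths), -pg$noise_sdlog^2 / 2,
                           pg$noise_sdlog))
        else 1
        pig_rows[[length(pig_rows) + 1]] <- data.frame(
          analyte = an, treatment = trt, time_point = t_lab,
          depth_cm = depths, value = model * noise)
      }
    }
  }
  sd_ <- config$sand
  bump_shape <- profile_window(g, 1, sd_$window[1], sd_$window[2],
                               ramp = sd_$ramp)
  bump <- approx(g$cell_centers, bump_shape, xout = depths, rule = 2)$y
  sand_rows <- list()
  for (trt in names(tp)) {
    base <- sd_$base + (if (trt == "bioturbated") sd_$bump * bump else 0)
    for (t_lab in tp[[trt]]) {
      idx <- idx + 1L
      noise <- if (sd_$noise_sd > 0)
        with_seed(child_seed(config$seed, idx),
                  rnorm(length(depths), 0, sd_$noise_sd))
      else 0
      sand_rows[[length(sand_rows) + 1]] <- data.frame(
        treatment = trt, time_point = t_lab, depth_cm = depths,
        fraction = pmin(pmax(base + noise, 0), 1))
    }
  }
  list(pigments = do.call(rbind, pig_rows),
       sand = do.call(rbind, sand_rows),
       truth = list(particle = pc, sand_bump = sd_$bump,
                    sand_window = sd_$window, profiles = truth_profiles))
}

#' Synthetic community scenario
#'
#' Defines per-domain lineage pools with depth-structured responses and
#' planted correlation clusters.  Each domain carries "surface" clusters
#' (logistic decline with depth) and "subsurface" clusters (the opposite
#' trend); classes within a planted cluster share a log-normal latent
#' factor calibrated to the target within-cluster correlation.  The
#' biologically impacted layer (BL, 12.5-25 cm) of the bioturbated arm is
#' depleted: total gene abundances drop by the configured folds (~2 orders
#' of magnitude for prokaryotes, ~1 for eukaryotes) and a fraction of
#' lineages is suppressed, lowering richness.
#'
#' @param target_rho target within-cluster Spearman correlation (0-1).
#' @param bl_fold_abundance named depletion folds (`prok`, `euk`), `>= 1`.
#' @param bl_richness_loss fraction of lineages suppressed in the BL of the
#'   bioturbated arm.
#' @param depth_reads range of per-sample read depths.
#' @param sample_depths sediment depths (cm) at which communities are
#'   sampled.
#' @return A list of class `"community_scenario"`.
#' @export
community_scenario <- function(target_rho = 0.8,
                               bl_fold_abundance = c(prok = 100, euk = 10),
                               bl_richness_loss = 0.35,
                               depth_reads = c(8000, 12000),
                               sample_depths = c(1, 3, 5, 7, 9, 11, 14, 17,
                                                 20, 23, 26, 28)) {
  if (target_rho <= 0 || target_rho >= 1)
    stop_invalid("`target_rho` must lie in (0, 1)")
  if (any(bl_fold_abundance < 1)) stop_invalid("depletion folds must be >= 1")
  mk <- function(clusters, type, midpoint, zpc)
    list(clusters = clusters, type = type, midpoint = midpoint,
         zotus_per_class = zpc)
  domains <- list(
    bac16S = mk(c(B1 = 4, B2 = 4, B3 = 4, B4 = 4),
                c(B1 = "surface", B2 = "surface",
                  B3 = "subsurface", B4 = "subsurface"),
                c(B1 = 5, B2 = 9, B3 = 16, B4 = 24), 6),
    arc16S = mk(c(A1 = 4, A2 = 4),
                c(A1 = "surface", A2 = "subsurface"),
                c(A1 = 7, A2 = 20), 5),
    euk18S = mk(c(E1 = 5, E2 = 5),
                c(E1 = "surface", E2 = "subsurface"),
                c(E1 = 6, E2 = 18), 5))
  structure(list(domains = domains, target_rho = target_rho,
                 bl_fold_abundance = bl_fold_abundance,
                 bl_richness_loss = bl_richness_loss,
                 depth_reads = depth_reads, sample_depths = sample_depths,
                 logistic_slope = 3, baseline = 0.02,
                 sigma_cluster = 0.8),
            class = "community_scenario")
}

domain_kingdom <- c(bac16S = "Bacteria", arc16S = "Archaea",
                    euk18S = "Eukarya")

#' Generate synthetic communities, trees and qPCR profiles
#'
#' Produces one [zotu_table()] and one random coalescent tree per domain,
#' plus a qPCR gene-abundance profile table, all seeded.  Per sample
#' (depth x treatment x time point) lineage weights follow the scenario's
#' logistic depth responses, multiplied by shared latent log-normal cluster
#' factors (the planted correlation structure); reads are drawn
#' multinomially at the configured depth.  The bioturbated BL receives the
#' scenario's abundance and richness depletion.
#'
#' @param scenario a [community_scenario()].
#' @param config a [scenario_config()] (supplies the seed and time points).
#' @return List with `tables` (per-domain [zotu_table()]), `trees`
#'   (per-domain `ape::phylo`), `genes` (qPCR data frame) and `truth`
#'   (planted clusters, suppressed lineages, depletion settings).
#' @export
generate_community <- function(scenario = community_scenario(),
                               config = scenario_config()) {
  stopifnot(inherits(scenario, "community_scenario"),
            inherits(config, "scenario_config"))
  tp <- list(bioturbated = c("T1", "T2", "T4"),
             nonbioturbated = c("T2", "T3", "T4"))
  depths <- scenario$sample_depths
  sig_c <- scenario$sigma_cluster
  sig_e <- sig_c * sqrt(1 / scenario$target_rho - 1)

  samples <- do.call(rbind, lapply(names(tp), function(trt)
    expand.grid(treatment = trt, time_point = tp[[trt]], depth_cm = depths,
                stringsAsFactors = FALSE)))
  samples$sample_id <- sprintf("%s_%s_d%04.1f", substr(samples$treatment, 1, 3),
                               samples$time_point, samples$depth_cm)
  samples$zone <- assign_zone(samples$depth_cm, samples$treatment)
  metadata <- data.frame(samples[c("depth_cm", "treatment", "time_point",
                                   "zone")],
                         row.names = samples$sample_id)
  in_bl_bio <- samples$treatment == "bioturbated" &
    samples$depth_cm >= 12.5 & samples$depth_cm < 25

  tables <- list(); trees <- list(); truth_clusters <- list()
  suppressed_all <- list()
  for (di in seq_along(scenario$domains)) {
    dom <- names(scenario$domains)[di]
    spec <- scenario$domains[[dom]]
    cluster_of_class <- rep(names(spec$clusters), spec$clusters)
    n_classes <- length(cluster_of_class)
    class_ids <- sprintf("c_%s_%02d", dom, seq_len(n_classes))
    zpc <- spec$zotus_per_class
    n_taxa <- n_classes * zpc
    taxa <- sprintf("Z_%s_%03d", dom, seq_len(n_taxa))
    class_of_taxon <- rep(class_ids, each = zpc)
    cluster_of_taxon <- rep(cluster_of_class, each = zpc)

    seed_dom <- child_seed(config$seed, 100 + di)
    sim <- with_seed(seed_dom, {
      base <- rlnorm(n_taxa, 0, 1)
      n_lost <- round(scenario$bl_richness_loss * n_taxa)
      suppressed <- sample(taxa, n_lost)
      counts <- matrix(0L, nrow(samples), n_taxa,
                       dimnames = list(samples$sample_id, taxa))
      reads <- round(runif(nrow(samples), scenario$depth_reads[1],
                           scenario$depth_reads[2]))
      for (s in seq_len(nrow(samples))) {
        d <- samples$depth_cm[s]
        curve <- vapply(seq_len(n_taxa), function(i) {
          cl <- cluster_of_taxon[i]
          m <- spec$midpoint[[cl]]
          val <- if (spec$type[[cl]] == "surface")
            plogis((m - d) / scenario$logistic_slope)
          else plogis((d - m) / scenario$logistic_slope)
          val + scenario$baseline
        }, numeric(1))
        z_cl <- rnorm(length(spec$clusters))
        names(z_cl) <- names(spec$clusters)
        w <- base * curve *
          exp(sig_c * z_cl[cluster_of_taxon] + sig_e * rnorm(n_taxa))
        if (in_bl_bio[s]) w[taxa %in% suppressed] <- w[taxa %in% suppressed] * 2e-3
        counts[s, ] <- as.integer(rmultinom(1, reads[s], w / sum(w)))
      }
      # guard: a multinomial draw can leave a sample empty only if reads = 0
      list(counts = counts, suppressed = suppressed,
           tree = ape::rcoal(n_taxa, tip.label = taxa))
    })
    taxonomy <- data.frame(
      domain = domain_kingdom[[dom]],
      phylum = paste0("p_", cluster_of_taxon),
      class = class_of_taxon,
      order = "unclassified", family = "unclassified",
      genus = "unclassified", row.names = taxa)
    tables[[dom]] <- zotu_table(sim$counts, taxonomy, metadata, dom)
    trees[[dom]] <- sim$tree
    truth_clusters[[dom]] <- setNames(cluster_of_class, class_ids)
    suppressed_all[[dom]] <- sim$suppressed
  }

  genes <- generate_gene_profile(scenario, config, samples)
  list(tables = tables, trees = trees, genes = genes,
       truth = list(class_clusters = truth_clusters,
                    suppressed = suppressed_all,
                    bl_fold_abundance = scenario$bl_fold_abundance,
                    bl_richness_loss = scenario$bl_richness_loss,
                    metadata = metadata))
}

# qPCR gene copies per g wet sediment along the sampled profile, with the
# BL depletion applied in the bioturbated arm and log-normal assay noise.
generate_gene_profile <- function(scenario, config, samples) {
  d <- samples$depth_cm
  surf <- function(scale_) 10^(-d / scale_)
  total16S <- function(bac, arc) bac + arc
  base <- data.frame(
    bac16S = 2e9 * surf(30),
    arc16S = 5e7 * surf(60),
    euk18S = 1e8 * surf(15),
    rbcL_ochrophyta = 2e7 * surf(8),
    rbcL_vascular = 3e3 * 10^(d / 40))
  t16 <- base$bac16S + base$arc16S
  frac_deep <- plogis((d - 12) / 4)
  base$dsrB <- t16 * (0.01 + 0.05 * frac_deep)
  base$soxB <- t16 * 0.02 * (1 - 0.7 * frac_deep)
  base$narG <- t16 * 0.015 * (1 - 0.7 * frac_deep)
  base$amoA <- t16 * 0.005 * (1 - 0.7 * frac_deep)
  in_bl <- samples$treatment == "bioturbated" & d >= 12.5 & d < 25
  prok <- c("bac16S", "arc16S", "dsrB", "soxB", "narG", "amoA")
  euk <- c("euk18S", "rbcL_ochrophyta", "rbcL_vascular")
  base[in_bl, prok] <- base[in_bl, prok] / scenario$bl_fold_abundance[["prok"]]
  base[in_bl, euk] <- base[in_bl, euk] / scenario$bl_fold_abundance[["euk"]]
  noisy <- with_seed(child_seed(config$seed, 500), {
    as.data.frame(lapply(base, function(col)
      col * rlnorm(length(col), -0.15^2 / 2, 0.15)))
  })
  cbind(samples[c("sample_id", "treatment", "time_point", "depth_cm", "zone")],
        noisy)
}

#' Parameter-recovery simulation study
#'
#' The built-in harness for assessing inversion bias and spread: for each
#' replicate, generates noisy synthetic porewater and pigment observations
#' with the scenario's true parameters and a replicate-specific seed, runs
#' the two-stage fits, and reports true vs estimated values.
#'
#' @param n_reps number of replicates.
#' @param config a [scenario_config()]; its `solutes`/`pigments` noise
#'   settings define the noise level.
#' @param what which fits to exercise.
#' @param seed master seed for the replicate stream.
#' @param n_starts multistarts per fit (defaults to the inversion default).
#' @return Data frame with `rep`, `parameter`, `true`, `estimate`.
#' @export
recovery_study <- function(n_reps = 50, config = scenario_config(),
                           what = c("porewater", "pigments"), seed = 1,
                           n_starts = 8) {
  what <- match.arg(what, several.ok = TRUE)
  out <- list()
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- child_seed(seed, r)
    inv <- inversion_config_from_scenario(cfg, n_starts = n_starts)
    if ("porewater" %in% what) {
      geo <- generate_geochem(cfg)
      obs <- geo$observations[geo$observations$time_point %in% c("T1", "T2"), ]
      fp <- fit_physical_porewater(obs[obs$treatment == "defaunated", ], inv)
      fb <- fit_bioirrigation(obs[obs$treatment == "refaunated", ], fp, inv)
      out[[length(out) + 1]] <- data.frame(
        rep = r,
        parameter = c("a_P", "L_P", "a_B", "z1", "z2"),
        true = unname(unlist(cfg$mixing[c("a_P", "L_P", "a_B", "z1", "z2")])),
        estimate = unname(c(fp$parameters, fb$parameters)))
    }
    if ("pigments" %in% what) {
      pig <- generate_pigments_grainsize(cfg)
      fm <- fit_particle_mixing(pig$pigments, inv)
      out[[length(out) + 1]] <- data.frame(
        rep = r,
        parameter = c("d_P", "L_DP", "d_B", "w1", "w2"),
        true = unname(unlist(cfg$particle[c("d_P", "L_DP", "d_B", "w1", "w2")])),
        estimate = unname(fm$parameters))
    }
  }
  do.call(rbind, out)
}
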