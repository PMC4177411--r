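#' Configuration for the triplet-matched cohort simulator
#'
#' The generator emulates a matched-triplet cutaneous 16S survey: for each
#' triplet one lesion and one contralateral unaffected sample from a patient
#' plus a site-matched control sample from a healthy subject. Communities are
#' drawn from a two-component mixture of latent community types
#' ("cutaneotypes"): type 1 Proteobacteria-dominated, type 2
#' Firmicutes/Actinobacteria-dominated. Skin type tilts (i) the mixture
#' weight, (ii) a multiplicative block on the four classical skin genera
#' (Corynebacterium, Propionibacterium, Staphylococcus, Streptococcus), and
#' (iii) the presence probability of two designated marker OTUs whose joint
#' ("double-positive") prevalence falls from control to unaffected to lesion.
#' Compositional noise is Dirichlet-multinomial with concentration `theta`;
#' read depth is discretised lognormal (median 8,621 by default).
#'
#' @param n_triplets Number of matched triplets (default 51).
#' @param n_otus,n_genera Taxonomic grain of the simulated table.
#' @param tree_seed,cohort_seed Integer seeds for the tree and the cohort.
#' @param depth_log_mean,depth_log_sd Lognormal read-depth parameters.
#' @param theta Dirichlet concentration (larger = less compositional
#'   overdispersion). Either a scalar (recycled over skin types) or a vector
#'   named by skin type. The default decreases from control to lesion,
#'   encoding the destabilised, more heterogeneous lesion communities
#'   (within-group dissimilarity lesion > unaffected > control).
#' @param type2_probability Named probability of latent type 2 per skin type.
#' @param skin_genera_multiplier Named multiplier on the four skin genera.
#' @param marker_double_prevalence Named double-positive rate per skin type.
#' @param marker_single_prevalence 2 x 3 matrix of per-marker single-positive
#'   rates (rows = marker OTUs, columns = skin types); must dominate the
#'   double-positive rate columnwise.
#' @param subject_effect_sd SD of the log-scale genus perturbation shared by
#'   the lesion and unaffected samples of a triplet (controls draw their own).
#' @param severity_coupling Slope linking a lesion sample's latent severity
#'   draw to extra marker depletion (0 = uncoupled).
#' @param severity_mean,severity_sd Named anchors (PASI, BSA, PGA) for the
#'   lognormal severity scores of lesion-bearing subjects.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_triplets = 51,
                              n_otus = 500,
                              n_genera = 40,
                              tree_seed = 20260101,
                              cohort_seed = 20260102,
                              depth_log_mean = log(8621),
                              depth_log_sd = 0.6,
                              theta = c(control = 60, unaffected = 45, lesion = 30),
                              type2_probability = c(control = 0.30, unaffected = 0.50, lesion = 0.60),
                              skin_genera_multiplier = c(control = 1.0, unaffected = 1.0, lesion = 1.6),
                              marker_double_prevalence = c(control = 0.78, unaffected = 0.53, lesion = 0.20),
                              marker_single_prevalence = rbind(
                                Gp4 = c(control = 0.80, unaffected = 0.61, lesion = 0.39),
                                Schlegelella = c(control = 0.96, unaffected = 0.69, lesion = 0.49)),
                              subject_effect_sd = 0.30,
                              severity_coupling = 0.5,
                              severity_mean = c(PASI = 8.7, BSA = 9.4, PGA = 6.6),
                              severity_sd = c(PASI = 10.1, BSA = 13.9, PGA = 6.9)) {
  if (length(theta) == 1) theta <- stats::setNames(rep(theta, 3), skin_type_levels())
  stopifnot(n_triplets >= 1, n_otus >= 3, n_genera >= 6, n_otus >= n_genera,
            all(theta > 0), setequal(names(theta), skin_type_levels()),
            subject_effect_sd >= 0,
            all(type2_probability >= 0 & type2_probability <= 1),
            all(skin_genera_multiplier > 0),
            all(marker_double_prevalence >= 0 & marker_double_prevalence <= 1),
            all(marker_single_prevalence >= 0 & marker_single_prevalence <= 1))
  for (g in skin_type_levels()) {
    if (any(marker_single_prevalence[, g] < marker_double_prevalence[g])) {
      stop("single-positive prevalence below double-positive for group ", g,
           call. = FALSE)
    }
  }
  structure(list(
    n_triplets = n_triplets, n_otus = n_otus, n_genera = n_genera,
    tree_seed = tree_seed, cohort_seed = cohort_seed,
    depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
    theta = theta,
    type2_probability = type2_probability,
    skin_genera_multiplier = skin_genera_multiplier,
    marker_double_prevalence = marker_double_prevalence,
    marker_single_prevalence = marker_single_prevalence,
    subject_effect_sd = subject_effect_sd,
    severity_coupling = severity_coupling,
    severity_mean = severity_mean, severity_sd = severity_sd
  ), class = "simulation_config")
}

#' Null (no skin-type effect) simulator configuration
#'
#' All skin types exchangeable: equal type-2 probability, unit skin-genera
#' multipliers, equal marker prevalence. Used for type-I-error calibration.
#'
#' @param ... Overrides passed to [simulation_config()].
#' @export
null_simulation_config <- function(...) {
  simulation_config(
    type2_probability = c(control = 0.4, unaffected = 0.4, lesion = 0.4),
    skin_genera_multiplier = c(control = 1, unaffected = 1, lesion = 1),
    marker_double_prevalence = c(control = 0.5, unaffected = 0.5, lesion = 0.5),
    marker_single_prevalence = rbind(
      Gp4 = c(control = 0.65, unaffected = 0.65, lesion = 0.65),
      Schlegelella = c(control = 0.8, unaffected = 0.8, lesion = 0.8)),
    theta = 50,
    severity_coupling = 0,
    ...)
}

# Run code with a private RNG stream; the caller's .Random.seed is restored.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) stop("degenerate Dirichlet draw (all-zero composition)", call. = FALSE)
  g / sum(g)
}

lognormal_pars <- function(mean, sd) {
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log1p(cv2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

skin_genera <- function() {
  c("Corynebacterium", "Propionibacterium", "Staphylococcus", "Streptococcus")
}

# Deterministic genus/OTU layout: phylum assignments, two-type base
# compositions over genera, within-genus OTU weights, marker designation.
genus_layout <- function(config) {
  named <- tibble::tibble(
    genus  = c("Corynebacterium", "Propionibacterium", "Staphylococcus",
               "Streptococcus", "Gp4", "Schlegelella", "Cupriavidus",
               "Methylobacterium", "Flavisolibacter"),
    family = c("Corynebacteriaceae", "Propionibacteriaceae", "Staphylococcaceae",
               "Streptococcaceae", "Gp4", "Comamonadaceae", "Burkholderiaceae",
               "Methylobacteriaceae", "Chitinophagaceae"),
    order  = c("Actinomycetales", "Actinomycetales", "Bacillales",
               "Lactobacillales", "Gp4", "Burkholderiales", "Burkholderiales",
               "Rhizobiales", "Sphingobacteriales"),
    class  = c("Actinobacteria", "Actinobacteria", "Bacilli", "Bacilli",
               "Acidobacteria_Gp4", "Betaproteobacteria", "Betaproteobacteria",
               "Alphaproteobacteria", "Sphingobacteria"),
    phylum = c("Actinobacteria", "Actinobacteria", "Firmicutes", "Firmicutes",
               "Acidobacteria", "Proteobacteria", "Proteobacteria",
               "Proteobacteria", "Bacteroidetes"))
  n_extra <- config$n_genera - nrow(named)
  if (n_extra < 0) stop("n_genera must be at least ", nrow(named), call. = FALSE)
  phyla <- c("Proteobacteria", "Firmicutes", "Actinobacteria",
             "Bacteroidetes", "Acidobacteria")
  extra_phylum <- rep(c("Proteobacteria", "Proteobacteria", "Firmicutes",
                        "Actinobacteria", "Bacteroidetes", "Acidobacteria"),
                      length.out = n_extra)
  extra <- tibble::tibble(
    genus  = sprintf("Genus%02d", seq_len(n_extra)),
    family = sprintf("Family%02d", seq_len(n_extra)),
    order  = paste0(extra_phylum, "ales"),
    class  = paste0(extra_phylum, "ia"),
    phylum = extra_phylum)
  gn <- dplyr::bind_rows(named, extra)
  gn$is_skin <- gn$genus %in% skin_genera()

  # Two-type base composition: phylum budgets split within phylum, the skin
  # genera taking a fixed dominant share of their phylum's budget.
  type_budget <- cbind(
    type1 = c(Proteobacteria = 0.55, Firmicutes = 0.12, Actinobacteria = 0.12,
              Bacteroidetes = 0.12, Acidobacteria = 0.09),
    type2 = c(Proteobacteria = 0.20, Firmicutes = 0.35, Actinobacteria = 0.30,
              Bacteroidetes = 0.10, Acidobacteria = 0.05))
  w <- matrix(0, nrow(gn), 2, dimnames = list(gn$genus, c("type1", "type2")))
  for (ph in phyla) {
    idx <- which(gn$phylum == ph)
    skin_idx <- idx[gn$is_skin[idx]]
    rest_idx <- setdiff(idx, skin_idx)
    share_skin <- if (length(skin_idx)) 0.70 else 0
    # geometric decay across the remaining genera of the phylum
    dec <- 0.75^(seq_along(rest_idx) - 1)
    for (ty in 1:2) {
      b <- type_budget[ph, ty]
      if (length(skin_idx)) w[skin_idx, ty] <- b * share_skin / length(skin_idx)
      if (length(rest_idx)) w[rest_idx, ty] <- b * (1 - share_skin) * dec / sum(dec)
    }
  }
  gn$w_type1 <- w[, 1] / sum(w[, 1])
  gn$w_type2 <- w[, 2] / sum(w[, 2])

  # OTU allocation: every genus gets at least one OTU, remainder round-robin;
  # within-genus weights decay geometrically; marker OTUs are the dominant
  # OTUs of the Gp4 and Schlegelella genera.
  sizes <- rep(1L, nrow(gn))
  extra_slots <- config$n_otus - nrow(gn)
  if (extra_slots > 0) {
    add <- table(factor(rep(seq_len(nrow(gn)), length.out = extra_slots),
                        levels = seq_len(nrow(gn))))
    sizes <- sizes + as.integer(add)
  }
  otus <- tibble::tibble(
    genus = rep(gn$genus, sizes),
    within_rank = unlist(lapply(sizes, seq_len)))
  otus$weight <- 0.6^(otus$within_rank - 1)
  otus$otu_id <- sprintf("OTU%05d", seq_len(nrow(otus)))
  otus$otu_id[otus$genus == "Gp4" & otus$within_rank == 1] <- "OTU3855"
  otus$otu_id[otus$genus == "Schlegelella" & otus$within_rank == 1] <- "OTU13613"
  otus$is_marker <- otus$otu_id %in% c("OTU3855", "OTU13613")
  list(genera = gn, otus = otus)
}

#' Simulate a random genus-structured phylogeny
#'
#' Pure-birth (Yule) backbone over genera with pure-birth subtrees grafted at
#' each genus tip, so the OTUs of a genus are always monophyletic;
#' branch lengths are redrawn i.i.d. exponential. Deterministic given the
#' seed.
#'
#' @param n_otus Number of tips.
#' @param tree_seed Integer seed.
#' @param genus_sizes Optional named integer vector of OTUs per genus; names
#'   become tip-label prefixes. Defaults to an even split into
#'   `min(40, n_otus)` genera with tips labelled `OTU00001, ...`.
#' @param rate Rate of the exponential branch-length distribution.
#' @return An `ape::phylo` tree with `n_otus` tips.
#' @export
make_tree <- function(n_otus, tree_seed, genus_sizes = NULL, rate = 5) {
  stopifnot(n_otus >= 3)
  if (is.null(genus_sizes)) {
    n_gen <- min(40L, n_otus)
    genus_sizes <- table(factor(rep(seq_len(n_gen), length.out = n_otus),
                                levels = seq_len(n_gen)))
    genus_sizes <- stats::setNames(as.integer(genus_sizes),
                                   sprintf("G%02d", seq_len(n_gen)))
    tips <- sprintf("OTU%05d", seq_len(n_otus))
  } else {
    tips <- NULL
  }
  with_seed(tree_seed, {
    labels <- split_tip_labels(genus_sizes, tips)
    tr <- grow_genus_tree(genus_sizes, labels)
    tr$edge.length <- stats::rexp(nrow(tr$edge), rate = rate)
    tr
  })
}

split_tip_labels <- function(genus_sizes, tips = NULL) {
  if (is.null(tips)) {
    tips <- unlist(mapply(function(g, n) sprintf("%s_OTU%03d", g, seq_len(n)),
                          names(genus_sizes), genus_sizes, SIMPLIFY = FALSE))
  }
  split(tips, rep(seq_along(genus_sizes), genus_sizes))
}

grow_genus_tree <- function(genus_sizes, labels) {
  n_gen <- length(genus_sizes)
  backbone <- if (n_gen >= 3) {
    ape::rphylo(n_gen, birth = 1, death = 0)
  } else if (n_gen == 2) {
    ape::read.tree(text = "(t1:1,t2:1);")
  } else {
    NULL
  }
  if (is.null(backbone)) {  # single genus: the subtree is the tree
    tr <- ape::rphylo(genus_sizes[1], birth = 1, death = 0)
    tr$tip.label <- labels[[1]]
    return(tr)
  }
  backbone$tip.label <- paste0("genus_", seq_len(n_gen))
  tr <- backbone
  for (i in seq_len(n_gen)) {
    tip_name <- paste0("genus_", i)
    if (genus_sizes[i] == 1) {
      tr$tip.label[tr$tip.label == tip_name] <- labels[[i]][1]
    } else {
      sub <- ape::rphylo(genus_sizes[i], birth = 1, death = 0)
      sub$tip.label <- labels[[i]]
      sub$root.edge <- 0.1
      tr <- ape::bind.tree(tr, sub, where = which(tr$tip.label == tip_name))
    }
  }
  tr
}

#' Simulate a triplet-matched cohort
#'
#' Draws `3 * n_triplets` samples under the model described in
#' [simulation_config()]. Returns the OTU count table, sample metadata,
#' taxonomy, phylogeny, and a ground-truth ledger (`truth`) recording latent
#' cutaneotypes, subject effects, marker presences, severity latents and
#' seeds, so recovery tests can assert against known answers.
#'
#' @param config A [simulation_config()].
#' @param week Longitudinal week label stored in the metadata (default 0).
#' @return A list of class `cohort_simulation` with elements `counts`,
#'   `metadata`, `taxonomy`, `tree`, `truth`.
#' @export
simulate_cohort <- function(config = simulation_config(), week = 0) {
  layout <- genus_layout(config)
  state <- with_seed(config$cohort_seed, cohort_state(config, layout))
  sim <- with_seed(config$cohort_seed + 7L,
                   draw_samples(config, layout, state, week = week))
  tree <- make_tree(config$n_otus, config$tree_seed,
                    genus_sizes = stats::setNames(
                      as.integer(table(factor(layout$otus$genus,
                                              levels = layout$genera$genus))),
                      layout$genera$genus))
  # graft carries genus labels; relabel tips to the layout's OTU ids
  lab_map <- split_tip_labels(stats::setNames(
    as.integer(table(factor(layout$otus$genus, levels = layout$genera$genus))),
    layout$genera$genus))
  names(lab_map) <- layout$genera$genus
  for (g in layout$genera$genus) {
    ids <- layout$otus$otu_id[layout$otus$genus == g]
    tree$tip.label[match(lab_map[[g]], tree$tip.label)] <- ids
  }
  taxonomy <- dplyr::left_join(layout$otus["otu_id"],
                               dplyr::left_join(layout$otus[c("otu_id", "genus")],
                                                layout$genera, by = "genus"),
                               by = "otu_id")
  taxonomy <- tibble::tibble(
    taxon_id = taxonomy$otu_id, phylum = taxonomy$phylum, class = taxonomy$class,
    order = taxonomy$order, family = taxonomy$family, genus = taxonomy$genus)
  structure(list(counts = sim$counts, metadata = sim$metadata,
                 taxonomy = taxonomy, tree = check_tree(tree),
                 truth = sim$truth), class = "cohort_simulation")
}

# Subject-level draws reused across longitudinal visits: demographics, sites,
# per-triplet genus effects (shared by lesion+unaffected), severity latents.
cohort_state <- function(config, layout) {
  n <- config$n_triplets
  n_gen <- nrow(layout$genera)
  sites <- c("body", "head", "upper extremity", "lower extremity")
  site <- sample(sites, n, replace = TRUE)
  micro <- ifelse(site %in% c("body", "head"), "sebaceous", "dry")
  months <- sprintf("%d-%02d", rep(2008:2009, each = 12), 1:12)
  list(
    site = site, micro = micro,
    month = sample(months, n, replace = TRUE),
    age_patient = pmin(80, pmax(18, round(stats::rnorm(n, 45, 14)))),
    age_control = pmin(80, pmax(18, round(stats::rnorm(n, 45, 14)))),
    gender_patient = sample(c("female", "male"), n, replace = TRUE),
    gender_control = sample(c("female", "male"), n, replace = TRUE),
    ethnicity_patient = sample(c("white", "black", "asian", "other"), n,
                               replace = TRUE, prob = c(.6, .15, .15, .1)),
    ethnicity_control = sample(c("white", "black", "asian", "other"), n,
                               replace = TRUE, prob = c(.6, .15, .15, .1)),
    history = stats::runif(n) < 0.3,
    effect_patient = matrix(stats::rnorm(n * n_gen, 0, config$subject_effect_sd),
                            n_gen, n),
    effect_control = matrix(stats::rnorm(n * n_gen, 0, config$subject_effect_sd),
                            n_gen, n),
    severity_z = stats::rnorm(n)
  )
}

draw_samples <- function(config, layout, state, week = 0,
                         multiplier_override = NULL, keep = NULL) {
  gn <- layout$genera
  ot <- layout$otus
  types <- skin_type_levels()
  mult <- multiplier_override %||% config$skin_genera_multiplier
  keep <- keep %||% seq_len(config$n_triplets)
  sev_pars <- lapply(seq_along(config$severity_mean), function(i)
    lognormal_pars(config$severity_mean[i], config$severity_sd[i]))
  names(sev_pars) <- names(config$severity_mean)

  rows <- list(); cnts <- list(); truths <- list()
  for (t in keep) {
    for (ty in types) {
      sid <- sprintf("T%02d_%s_w%02d", t, ty, week)
      subject <- if (ty == "control") sprintf("C%02d", t) else sprintf("P%02d", t)
      eff <- if (ty == "control") state$effect_control[, t] else state$effect_patient[, t]
      type2 <- stats::runif(1) < config$type2_probability[ty]
      base <- if (type2) gn$w_type2 else gn$w_type1
      pg <- base * exp(eff)
      pg[gn$is_skin] <- pg[gn$is_skin] * mult[ty]
      pg <- pg / sum(pg)

      p_otu <- pg[match(ot$genus, gn$genus)] * ot$weight
      # severity latent couples to extra marker depletion in lesion samples
      z <- if (ty == "lesion") state$severity_z[t] else 0
      dp_prob <- config$marker_double_prevalence[ty]
      sp <- config$marker_single_prevalence[, ty]
      if (ty == "lesion" && config$severity_coupling > 0) {
        shift <- function(p) stats::plogis(stats::qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6)) -
                                             config$severity_coupling * z)
        dp_prob <- shift(dp_prob); sp <- shift(sp)
        sp <- pmax(sp, dp_prob)
      }
      dp <- stats::runif(1) < dp_prob
      resid <- ifelse(dp_prob < 1, (sp - dp_prob) / (1 - dp_prob), 0)
      present <- dp | (stats::runif(2) < resid)
      names(present) <- rownames(config$marker_single_prevalence)
      marker_ids <- c("OTU3855", "OTU13613")
      for (k in 1:2) if (!present[k]) p_otu[ot$otu_id == marker_ids[k]] <- 0
      p_otu <- p_otu / sum(p_otu)

      comp <- rdirichlet1(config$theta[[ty]] * p_otu)
      depth <- max(1L, round(stats::rlnorm(1, config$depth_log_mean, config$depth_log_sd)))
      cnt <- stats::rmultinom(1, depth, comp)[, 1]

      sev <- c(PASI = NA_real_, BSA = NA_real_, PGA = NA_real_)
      if (ty != "control") {
        zz <- state$severity_z[t]
        for (s in names(sev)) {
          e2 <- stats::rnorm(1, 0, 0.5)
          sev[s] <- round(exp(sev_pars[[s]]$meanlog +
                                sev_pars[[s]]$sdlog * (0.8 * zz + 0.6 * e2)), 1)
        }
      }
      rows[[sid]] <- tibble::tibble(
        sample_id = sid, skin_type = ty, triplet_id = sprintf("T%02d", t),
        subject_id = subject, body_site = state$site[t],
        microenvironment = state$micro[t], sample_month_year = state$month[t],
        age = if (ty == "control") state$age_control[t] else state$age_patient[t],
        gender = if (ty == "control") state$gender_control[t] else state$gender_patient[t],
        ethnicity = if (ty == "control") state$ethnicity_control[t] else state$ethnicity_patient[t],
        family_history = if (ty == "control") FALSE else state$history[t],
        PASI = sev["PASI"], BSA = sev["BSA"], PGA = sev["PGA"], week = week)
      cnts[[sid]] <- cnt
      truths[[sid]] <- tibble::tibble(
        sample_id = sid, skin_type = ty, triplet_id = sprintf("T%02d", t),
        cutaneotype = if (type2) 2L else 1L, depth = depth,
        marker_gp4 = present[1], marker_schlegelella = present[2],
        double_positive = dp, severity_z = z)
    }
  }
  m <- do.call(cbind, cnts)
  rownames(m) <- ot$otu_id
  metadata <- dplyr::bind_rows(rows)
  metadata$skin_type <- factor(metadata$skin_type, levels = types)
  truth <- list(
    samples = dplyr::bind_rows(truths),
    otus = tibble::tibble(otu_id = ot$otu_id, genus = ot$genus,
                          is_skin_genus = ot$genus %in% skin_genera(),
                          is_marker = ot$is_marker),
    multiplier = mult,
    config = config)
  list(counts = as_count_tbl(m), metadata = metadata, truth = truth)
}

#' Simulate a longitudinal follow-up cohort
#'
#' Week 0 reuses the cross-sectional model; later visits shrink the lesion
#' and unaffected skin-genera multipliers toward the control value by
#' `treatment_effect` per visit (1 = full normalisation by the next visit),
#' optionally with a transient overshoot of the unaffected multiplier at week
#' 12. Subject identities, demographics and subject effects are shared across
#' weeks; attrition keeps the leading `attrition[w]` triplets per week
#' (default 17/17/9).
#'
#' @param config A [simulation_config()]; its `n_triplets` caps the cohort.
#' @param weeks Subset of `c(0, 12, 36)`.
#' @param treatment_effect Fractional shrinkage toward control per visit.
#' @param overshoot Transient multiplicative bump of the unaffected
#'   multiplier at week 12 (0 = off).
#' @param attrition Named triplet counts per week.
#' @return Named list (one `cohort_simulation` per week).
#' @export
simulate_longitudinal <- function(config = simulation_config(n_triplets = 17),
                                  weeks = c(0, 12, 36),
                                  treatment_effect = 0.5,
                                  overshoot = 0,
                                  attrition = c("0" = 17, "12" = 17, "36" = 9)) {
  if (!all(weeks %in% c(0, 12, 36))) {
    stop("weeks must be a subset of {0, 12, 36}", call. = FALSE)
  }
  layout <- genus_layout(config)
  state <- with_seed(config$cohort_seed, cohort_state(config, layout))
  tmpl <- simulate_cohort(config)  # for tree/taxonomy reuse
  out <- list()
  for (w in sort(weeks)) {
    visit <- match(w, c(0, 12, 36)) - 1L
    shrink <- (1 - treatment_effect)^visit
    mult <- config$skin_genera_multiplier
    ctrl <- mult["control"]
    mult["lesion"] <- ctrl + (mult["lesion"] - ctrl) * shrink
    mult["unaffected"] <- ctrl + (mult["unaffected"] - ctrl) * shrink
    if (w == 12 && overshoot > 0) {
      mult["unaffected"] <- mult["unaffected"] * (1 + overshoot)
    }
    n_keep <- min(config$n_triplets, attrition[as.character(w)])
    sim <- with_seed(config$cohort_seed + 7L + 1000L * w,
                     draw_samples(config, layout, state, week = w,
                                  multiplier_override = mult,
                                  keep = seq_len(n_keep)))
    out[[as.character(w)]] <- structure(
      list(counts = sim$counts, metadata = sim$metadata,
           taxonomy = tmpl$taxonomy, tree = tmpl$tree, truth = sim$truth),
      class = "cohort_simulation")
  }
  out
}

#' Write a simulated cohort to disk in the package's file formats
#'
#' @param sim A `cohort_simulation`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(sim$counts, file.path(dir, "otu_table.tsv"))
  write_tree(sim$tree, file.path(dir, "tree.nwk"))
  write_tsv_table(sim$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_tsv_table(sim$metadata, file.path(dir, "metadata.tsv"))
  jsonlite::write_json(
    list(samples = sim$truth$samples, otus = sim$truth$otus,
         config = unclass(sim$truth$config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
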