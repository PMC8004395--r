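# Synthetic cohort generators. Every pipeline input (food composition
# table, 4-day diaries, MSP gene counts, clinical table, functional
# profiles) can be generated with planted statistical structure, so each
# downstream stage has a recoverable ground truth.

# Fixed hierarchy skeleton for the synthetic food database.
.food_hierarchy <- list(
  "animal-based" = list(meat   = c("red_meat", "poultry", "cured_meat"),
                        fish   = c("fatty_fish", "lean_fish"),
                        dairy  = c("cheese", "milk_products"),
                        eggs   = c("egg_dishes")),
  "plant-based"  = list(vegetables = c("root_vegetables", "leafy_vegetables"),
                        fruits     = c("fresh_fruit", "fruit_products"),
                        grains     = c("bread", "cereals"),
                        legumes    = c("beans_lentils")),
  alcohol        = list(alcoholic_drinks = c("beer_wine", "spirits")),
  fats           = list(added_fats = c("oils", "spreads")),
  others         = list(sweets    = c("candy", "pastry"),
                        beverages = c("soft_drinks", "hot_drinks"),
                        composite = c("mixed_dishes"))
)

.level2_weights <- c("animal-based" = 0.30, "plant-based" = 0.40,
                     alcohol = 0.05, fats = 0.08, others = 0.17)

#' Generate a synthetic food composition database
#'
#' Emulates a national food composition table: items carry a 4-level
#' hierarchy (level 2 one of animal-based / plant-based / alcohol / fats /
#' others; levels 3-4 from a fixed category skeleton), per-100 g nutrient
#' contents, energy, a drink flag and a fruit/vegetable percentage. Within
#' every level-4 category the macronutrient compositions are drawn from at
#' least two distinct Dirichlet components, so that the nutrient-based
#' subcategory split of [build_food_tree()] has real structure to find.
#'
#' @param n_items number of food items (>= 10).
#' @param n_nutrients number of nutrient composition columns (>= 4); the
#'   first four are protein, fat, carbohydrate and fibre, further columns
#'   are minor components. Sugar, saturated fat, sodium, energy, fructose
#'   and monosaccharide columns are always derived in addition.
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return data.frame with one row per item: `item_id`, `level2`..`level4`,
#'   nutrient columns (g/100 g), `sugar_g`, `satfat_g`, `sodium_mg`,
#'   `energy_kj`, `energy_kcal`, `fructose_g`, `monosacch_g`,
#'   `fruitveg_pct`, `is_drink`, and the generating component id
#'   `true_component` (bookkeeping, not used by the pipeline).
#' @export
gen_food_db <- function(n_items, n_nutrients = 8L, seed = 1L) {
  if (length(n_items) != 1L || n_items < 10)
    stop("n_items must be a single value >= 10", call. = FALSE)
  if (length(n_nutrients) != 1L || n_nutrients < 4)
    stop("n_nutrients must be a single value >= 4", call. = FALSE)
  n_items <- as.integer(n_items); n_nutrients <- as.integer(n_nutrients)
  nutr_names <- c("protein_g", "fat_g", "carb_g", "fiber_g",
                  if (n_nutrients > 4)
                    paste0("minor", seq_len(n_nutrients - 4L), "_g"))

  lvl4_tab <- do.call(rbind, lapply(names(.food_hierarchy), function(l2) {
    do.call(rbind, lapply(names(.food_hierarchy[[l2]]), function(l3) {
      data.frame(level2 = l2, level3 = l3,
                 level4 = .food_hierarchy[[l2]][[l3]])
    }))
  }))

  with_seed(seed, {
    # allocate items to level-4 categories, biased by level-2 weights and
    # guaranteeing >= 2 items per category where possible
    w4 <- .level2_weights[lvl4_tab$level2]
    idx <- rep(seq_len(nrow(lvl4_tab)), length.out = min(2L * nrow(lvl4_tab), n_items))
    if (n_items > length(idx))
      idx <- c(idx, sample(seq_len(nrow(lvl4_tab)), n_items - length(idx),
                           replace = TRUE, prob = w4))
    idx <- sample(idx)
    db <- lvl4_tab[idx, , drop = FALSE]
    rownames(db) <- NULL
    db$item_id <- sprintf("item_%04d", seq_len(n_items))

    # per level-4 category: 2-3 Dirichlet nutrient components
    db$true_component <- NA_character_
    nutr <- matrix(0, n_items, n_nutrients, dimnames = list(NULL, nutr_names))
    for (l4 in unique(db$level4)) {
      rows <- which(db$level4 == l4)
      n_comp <- sample(2:3, 1L)
      base <- matrix(stats::rgamma(n_comp * n_nutrients, shape = 0.8), n_comp)
      base <- base / rowSums(base)
      prec <- 150
      comp <- sample.int(n_comp, length(rows), replace = TRUE)
      for (i in seq_along(rows)) {
        g <- stats::rgamma(n_nutrients, shape = base[comp[i], ] * prec + 0.05)
        p <- g / sum(g)
        total <- stats::runif(1, 15, 55)            # g solids per 100 g
        nutr[rows[i], ] <- round(p * total, 2)
      }
      db$true_component[rows] <- paste0(l4, "_c", comp)
    }
    db <- cbind(db, as.data.frame(nutr))

    db$is_drink <- db$level3 %in% c("beverages", "alcoholic_drinks") |
      db$level4 %in% c("milk_products")
    db$is_drink <- db$is_drink & stats::runif(n_items) < 0.9
    # drinks are mostly water
    scale_drink <- ifelse(db$is_drink, stats::runif(n_items, 0.1, 0.4), 1)
    db[nutr_names] <- db[nutr_names] * scale_drink

    db$sugar_g <- round(db$carb_g * stats::rbeta(n_items, 2, 2) *
                          ifelse(db$level3 %in% c("sweets", "beverages", "fruits"),
                                 1, 0.5), 2)
    db$monosacch_g <- round(db$sugar_g * stats::rbeta(n_items, 4, 2), 2)
    db$fructose_g <- round(db$monosacch_g * stats::rbeta(n_items, 2, 2), 2)
    db$satfat_g <- round(db$fat_g * stats::rbeta(n_items, 2,
                                                 ifelse(db$level2 == "animal-based", 2, 4)), 2)
    db$sodium_mg <- round(ifelse(db$level4 %in% c("cured_meat", "cheese", "bread",
                                                  "mixed_dishes", "candy"),
                                 stats::rlnorm(n_items, log(450), 0.6),
                                 stats::rlnorm(n_items, log(80), 0.9)), 1)
    db$fruitveg_pct <- ifelse(db$level3 %in% c("vegetables", "fruits", "legumes"),
                              round(stats::runif(n_items, 55, 100), 1), 0)
    alcohol_g <- ifelse(db$level2 == "alcohol", stats::runif(n_items, 3, 12), 0)
    db$energy_kcal <- round(4 * db$protein_g + 9 * db$fat_g + 4 * db$carb_g +
                              2 * db$fiber_g + 7 * alcohol_g, 1)
    db$energy_kcal <- pmax(db$energy_kcal, 5)
    db$energy_kj <- round(db$energy_kcal * 4.184, 1)
    db[, c("item_id", "level2", "level3", "level4", "true_component",
           nutr_names, "sugar_g", "satfat_g", "sodium_mg", "fruitveg_pct",
           "fructose_g", "monosacch_g", "energy_kcal", "energy_kj", "is_drink")]
  })
}

# Nutrient composition columns of a food DB (the DMM features).
food_db_nutrient_cols <- function(food_db) {
  cand <- grep("^(protein|fat|carb|fiber|minor[0-9]+)_g$", names(food_db),
               value = TRUE)
  if (length(cand) < 2) stop("food_db has no nutrient composition columns")
  cand
}

#' Generate 4-day diet diaries with planted diet gradients
#'
#' Each subject gets a latent meat-plant score (positive tilts item choice
#' towards animal-based level-2 items, negative towards plant-based) and a
#' latent diet-quality score oriented so that HIGHER values mean a
#' preference for nutritionally poorer (higher FSA-NPS) items. Four days of
#' breakfast/lunch/dinner (plus optional snacks) are drawn per subject;
#' grams are log-normal and each subject's intake is calibrated to a
#' plausible daily energy (so the generated cohort passes
#' [filter_implausible_energy()]).
#'
#' @param food_db a food composition table from [gen_food_db()].
#' @param n_subjects number of subjects (>= 4).
#' @param gradient_sd standard deviation of the meat-plant latent; 0 makes
#'   all subjects exchangeable.
#' @param seed integer seed.
#' @param quality_sd standard deviation of the diet-quality latent.
#' @param mean_kcal,sd_kcal calibration target for mean daily energy.
#' @return list with `diary` (subject, day, meal, is_main_meal, item_id,
#'   grams) and `truth` (a `synthetic_truth` object whose `subject_latents`
#'   holds meat_plant_score, quality_score and the derived gas_score).
#' @export
gen_diaries <- function(food_db, n_subjects, gradient_sd = 1, seed = 1L,
                        quality_sd = 1, mean_kcal = 2100, sd_kcal = 300) {
  if (is.null(food_db) || nrow(food_db) == 0)
    stop("food_db is empty", call. = FALSE)
  if (n_subjects < 4) stop("n_subjects must be >= 4", call. = FALSE)
  grids <- fsanps_default_grids()
  item_score <- vapply(seq_len(nrow(food_db)), function(i)
    fsanps_item_score(food_db[i, ], food_db$fruitveg_pct[i], grids), numeric(1))
  score_z <- as.numeric(scale(item_score))
  mp_dir <- ifelse(food_db$level2 == "animal-based", 1,
                   ifelse(food_db$level2 == "plant-based", -1, 0))

  with_seed(seed, {
    subjects <- sprintf("subj_%03d", seq_len(n_subjects))
    mp <- stats::rnorm(n_subjects, 0, gradient_sd)
    qs <- stats::rnorm(n_subjects, 0, quality_sd)
    gas <- 0.6 * mp + 0.8 * stats::rnorm(n_subjects)
    rows <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      w <- exp(mp[s] * mp_dir + 0.8 * qs[s] * score_z)
      recs <- list()
      for (day in 1:4) {
        n_snack <- stats::rbinom(1L, 2L, 0.5)
        meals <- c("breakfast", "lunch", "dinner",
                   if (n_snack > 0) paste0("snack", seq_len(n_snack)))
        for (meal in meals) {
          main <- meal %in% c("breakfast", "lunch", "dinner")
          n_it <- if (main) 2L + stats::rpois(1L, 2) else 1L + stats::rbinom(1L, 1L, 0.5)
          n_it <- min(n_it, nrow(food_db))
          it <- sample.int(nrow(food_db), n_it, replace = FALSE, prob = w)
          recs[[length(recs) + 1L]] <- data.frame(
            subject = subjects[s], day = day, meal = meal,
            is_main_meal = main, item_id = food_db$item_id[it],
            grams = round(stats::rlnorm(n_it, log(110), 0.45), 1))
        }
      }
      d <- do.call(rbind, recs)
      # calibrate to a plausible mean daily energy
      kcal100 <- food_db$energy_kcal[match(d$item_id, food_db$item_id)]
      daily <- sum(d$grams * kcal100 / 100) / 4
      target <- min(max(stats::rnorm(1, mean_kcal, sd_kcal), 1000), 4200)
      d$grams <- round(d$grams * target / daily, 1)
      d$grams <- pmax(d$grams, 1)
      rows[[s]] <- d
    }
    diary <- do.call(rbind, rows)
    rownames(diary) <- NULL
    truth <- new_synthetic_truth(
      subject_latents = data.frame(subject = subjects, meat_plant_score = mp,
                                   quality_score = qs, gas_score = gas),
      seed = seed)
    list(diary = diary, truth = truth)
  })
}

#' Construct a synthetic-truth bookkeeping object
#'
#' @param subject_latents data.frame with one row per subject.
#' @param seed generating seed.
#' @param subspecies_labels optional sample x MSP label table.
#' @param coupling_effects optional named numeric effect sizes.
#' @return object of class `synthetic_truth`.
#' @export
new_synthetic_truth <- function(subject_latents, seed,
                                subspecies_labels = NULL,
                                coupling_effects = NULL) {
  structure(list(subject_latents = subject_latents,
                 subspecies_labels = subspecies_labels,
                 coupling_effects = coupling_effects,
                 seed = seed),
            class = "synthetic_truth")
}

#' Generate MSP gene counts with planted subspecies
#'
#' Builds an MSP catalog (core and accessory gene sets) and a gene-by-sample
#' coverage matrix. Each MSP's accessory genes are organised into disjoint
#' blocks, one per planted subspecies; in a detected sample the genes of the
#' sample's assigned block get coverage in the same band as the core genes
#' while other blocks stay at zero. A configurable fraction of samples is
#' left undetected (median core coverage <= 2) per MSP.
#'
#' @param n_samples number of samples.
#' @param n_msp number of MSPs.
#' @param subspecies_spec list of length `n_msp`; each element either an
#'   integer vector of accessory block sizes (0 or 1 block means no planted
#'   split) or a list of explicit disjoint accessory-gene index vectors.
#' @param seed integer seed.
#' @param n_core core genes per MSP (>= 10).
#' @param n_acc_background accessory genes outside any block.
#' @param undetected_frac expected fraction of undetected samples per MSP.
#' @param truth optional `synthetic_truth` from [gen_diaries()]; when given,
#'   samples are the truth's subjects, MSP abundances are tilted by the
#'   meat-plant latent with strength `coupling`, and the first MSP with >= 2
#'   blocks has its subspecies assignment driven by the same latent
#'   (abundance itself left diet-neutral), so subspecies-level analyses can
#'   out-resolve species-level ones.
#' @param coupling abundance tilt per unit of meat-plant latent.
#' @return list with `counts` (genes x samples), `catalog` (see
#'   [MSPCatalog][msp_core_abundance]), `truth` (subspecies labels, detected
#'   flags and per-sample abundances as generated).
#' @export
gen_msp_metagenome <- function(n_samples, n_msp, subspecies_spec = NULL,
                               seed = 1L, n_core = 30L,
                               n_acc_background = 10L,
                               undetected_frac = 0.1,
                               truth = NULL, coupling = 0) {
  if (n_samples < 2 || n_msp < 1) stop("non-positive sizes", call. = FALSE)
  if (n_core < 10) stop("each MSP needs >= 10 core genes", call. = FALSE)
  if (is.null(subspecies_spec))
    subspecies_spec <- rep(list(c(25L, 25L)), n_msp)
  if (length(subspecies_spec) != n_msp)
    stop("subspecies_spec must have one entry per MSP", call. = FALSE)

  if (!is.null(truth)) {
    samples <- truth$subject_latents$subject
    if (length(samples) != n_samples)
      stop("truth does not cover n_samples subjects", call. = FALSE)
    mp <- truth$subject_latents$meat_plant_score
  } else {
    samples <- sprintf("sample_%03d", seq_len(n_samples))
    mp <- rep(0, n_samples)
  }

  # normalize spec entries to explicit disjoint index blocks
  blocks_of <- lapply(subspecies_spec, function(sp) {
    if (is.list(sp)) {
      idx <- unlist(sp)
      if (anyDuplicated(idx) > 0)
        stop("overlapping accessory blocks", call. = FALSE)
      lapply(sp, as.integer)
    } else {
      sp <- as.integer(sp)
      if (any(sp < 0)) stop("negative block size", call. = FALSE)
      sp <- sp[sp > 0]
      if (length(sp) == 0) return(list())
      ends <- cumsum(sp)
      mapply(function(a, b) seq.int(a, b), c(1L, utils::head(ends, -1) + 1L),
             ends, SIMPLIFY = FALSE)
    }
  })

  with_seed(seed, {
    diet_msp <- if (!is.null(truth) && coupling != 0)
      which(vapply(blocks_of, length, integer(1)) >= 2)[1] else NA_integer_
    msp_ids <- sprintf("msp_%04d", seq_len(n_msp))
    counts_list <- list()
    catalog <- list()
    labels <- matrix(NA_integer_, n_samples, n_msp,
                     dimnames = list(samples, msp_ids))
    detected <- matrix(FALSE, n_samples, n_msp,
                       dimnames = list(samples, msp_ids))
    abundance <- matrix(0, n_samples, n_msp,
                        dimnames = list(samples, msp_ids))
    for (m in seq_len(n_msp)) {
      blocks <- blocks_of[[m]]
      n_block_genes <- if (length(blocks)) max(unlist(blocks)) else 0L
      n_acc <- n_block_genes + n_acc_background
      core_ids <- sprintf("%s_core_%03d", msp_ids[m], seq_len(n_core))
      acc_ids <- if (n_acc > 0) sprintf("%s_acc_%03d", msp_ids[m], seq_len(n_acc))
      catalog[[msp_ids[m]]] <- list(core = core_ids, accessory = acc_ids,
                                    blocks = lapply(blocks, function(b) acc_ids[b]))
      base <- stats::rnorm(1, log(12), 0.3)
      r_m <- if (!is.na(diet_msp) && m == diet_msp) 0 else
        coupling * stats::rnorm(1, 0, 1)
      a <- exp(base + r_m * mp + stats::rnorm(n_samples, 0, 0.35))
      det <- stats::runif(n_samples) >= undetected_frac
      a[det] <- pmax(a[det], 3.5)
      a[!det] <- stats::runif(sum(!det), 0.1, 0.9)
      abundance[, m] <- a
      detected[, m] <- det
      mat <- matrix(0, n_core + n_acc, n_samples,
                    dimnames = list(c(core_ids, acc_ids), samples))
      mat[seq_len(n_core), ] <- t(a * matrix(stats::rlnorm(n_samples * n_core, 0, 0.2),
                                             n_samples, n_core))
      if (length(blocks) >= 1) {
        lab <- if (!is.na(diet_msp) && m == diet_msp) {
          p1 <- stats::plogis(1.6 * mp)
          ifelse(stats::runif(n_samples) < p1, 1L,
                 1L + sample.int(length(blocks) - 1L, n_samples, replace = TRUE))
        } else sample.int(length(blocks), n_samples, replace = TRUE)
        labels[, m] <- lab
        for (s in seq_len(n_samples)) {
          if (!det[s]) next
          b <- blocks[[lab[s]]]
          mat[n_core + b, s] <- a[s] * stats::rlnorm(length(b), 0, 0.2)
        }
      }
      if (n_acc_background > 0) {
        bg <- n_core + n_block_genes + seq_len(n_acc_background)
        for (s in which(det)) {
          on <- stats::runif(n_acc_background) < 0.5
          mat[bg[on], s] <- a[s] * stats::rlnorm(sum(on), 0, 0.2)
        }
      }
      # undetected samples: uniformly low residual coverage
      for (s in which(!det))
        mat[, s] <- a[s] * stats::rlnorm(nrow(mat), 0, 0.3) *
          stats::rbinom(nrow(mat), 1L, 0.6)
      counts_list[[m]] <- round(mat, 3)
    }
    counts <- do.call(rbind, counts_list)
    tr <- new_synthetic_truth(
      subject_latents = if (!is.null(truth)) truth$subject_latents else
        data.frame(subject = samples, meat_plant_score = mp),
      seed = seed, subspecies_labels = labels,
      coupling_effects = c(abundance_coupling = coupling))
    tr$detected <- detected
    tr$abundance <- abundance
    tr$diet_coupled_msp <- if (!is.na(diet_msp)) msp_ids[diet_msp] else NA_character_
    list(counts = counts, catalog = catalog, truth = tr)
  })
}

#' Generate a synthetic clinical table from planted latents
#'
#' Symptom-severity groups (healthy/mild/moderate/severe, coded 1-4) are
#' monotone in the diet-quality latent plus noise; exhaled H2 and CH4 follow
#' a log-linear model in the meat-plant and gas latents; enterotype is a
#' noisy 3-level discretisation of the meat-plant latent.
#'
#' @param truth `synthetic_truth` with subject latents.
#' @param effects named list of effect sizes: `severity_quality`,
#'   `h2_gas`, `ch4_gas`, `h2_meat` (see details in the package vignette).
#' @param noise_sd standard deviation of the severity noise.
#' @param seed integer seed.
#' @param subjects optional subject subset; unknown subjects error.
#' @return data.frame: subject, severity_group (1-4), severity_label, h2,
#'   ch4, bmi, age, sex, enterotype.
#' @export
gen_clinical <- function(truth, effects = list(), noise_sd = 0.5, seed = 1L,
                         subjects = NULL) {
  eff <- utils::modifyList(list(severity_quality = 1.2, h2_gas = 0.6,
                                ch4_gas = -0.6, h2_meat = 0.2), effects)
  lat <- truth$subject_latents
  if (is.null(subjects)) subjects <- lat$subject
  miss <- setdiff(subjects, lat$subject)
  if (length(miss))
    stop("unknown subject(s): ", paste(miss, collapse = ", "), call. = FALSE)
  lat <- lat[match(subjects, lat$subject), ]
  gas <- lat$gas_score %||% rep(0, nrow(lat))
  with_seed(seed, {
    sev_lat <- eff$severity_quality * lat$quality_score +
      stats::rnorm(nrow(lat), 0, noise_sd)
    grp <- cut(sev_lat, breaks = stats::quantile(sev_lat, c(0, .25, .5, .75, 1)),
               labels = FALSE, include.lowest = TRUE)
    if (stats::sd(sev_lat) == 0) grp <- rep(1L, nrow(lat))
    h2 <- exp(1.6 + eff$h2_gas * gas + eff$h2_meat * lat$meat_plant_score +
                stats::rnorm(nrow(lat), 0, 0.3))
    ch4 <- exp(1.6 + eff$ch4_gas * gas + stats::rnorm(nrow(lat), 0, 0.3))
    et_lat <- 0.8 * lat$meat_plant_score + stats::rnorm(nrow(lat))
    enterotype <- cut(et_lat, stats::quantile(et_lat, c(0, 1/3, 2/3, 1)),
                      labels = FALSE, include.lowest = TRUE)
    data.frame(subject = subjects,
               severity_group = as.integer(grp),
               severity_label = c("healthy", "mild", "moderate", "severe")[grp],
               h2 = round(h2, 2), ch4 = round(ch4, 2),
               bmi = round(stats::rnorm(nrow(lat), 24.5, 3.5), 1),
               age = sample(20:70, nrow(lat), replace = TRUE),
               sex = sample(c("F", "M"), nrow(lat), replace = TRUE),
               enterotype = as.integer(enterotype))
  })
}

#' Generate CAZy and hydrogenase functional profiles with planted coupling
#'
#' Emulates per-sample relative abundance tables of carbohydrate-active
#' enzyme (CAZy) families and of hydrogenase groups classified by active
#' metal site. One hydrogenase group ([FeFe] A3) and a fixed set of
#' animal-carbohydrate CAZy families are driven by the same gas-metabolism
#' latent; [FeFe] A3 is additionally enriched in severe samples when a
#' severity vector is supplied. Gene-level counts (3 genes per family) and
#' the gene-to-family annotation maps are emitted alongside.
#'
#' @param truth `synthetic_truth` carrying `gas_score`, or `NULL`.
#' @param n_samples used when `truth` is `NULL`.
#' @param n_cazy number of CAZy families (>= 10).
#' @param n_animal number of animal-carbohydrate families coupled to the
#'   latent (default 8).
#' @param coupling per-unit-latent log-abundance shift of coupled families.
#' @param severe optional logical vector marking severe samples; adds
#'   `severity_shift` to the [FeFe] A3 log-abundance.
#' @param severity_shift log-abundance enrichment of [FeFe] A3 in severe.
#' @param noise_sd log-scale noise of the variable (non-dominant) families.
#' @param seed integer seed.
#'
#' @details The composition mimics gut functional profiles: a few dominant,
#' stable families (housekeeping plant-cell-wall degraders, the major
#' hydrogenase groups) carry most of the relative-abundance mass, while the
#' latent-coupled families are rare and variable. Keeping the coupled
#' families a small share of the total prevents compositional closure from
#' inducing spurious correlations between unrelated families.
#' @return list with `cazy` and `hydro` relative-abundance matrices
#'   (samples x families), `substrate_map` (family -> substrate category),
#'   `gene_counts`, `gene_map` (gene -> family, universe), and `truth`
#'   (planted edges and the latent used).
#' @export
gen_function_tables <- function(truth = NULL, n_samples = NULL,
                                n_cazy = 30L, n_animal = 8L,
                                coupling = 1.0, severe = NULL,
                                severity_shift = 1.2, noise_sd = 0.45,
                                seed = 1L) {
  if (n_cazy < 10 + n_animal + 5)
    stop("n_cazy must leave room for dominant and background families",
         call. = FALSE)
  if (!is.null(truth)) {
    samples <- truth$subject_latents$subject
    g <- truth$subject_latents$gas_score %||%
      stop("truth lacks gas_score", call. = FALSE)
  } else {
    if (is.null(n_samples)) stop("need truth or n_samples", call. = FALSE)
    samples <- sprintf("sample_%03d", seq_len(n_samples))
    g <- NULL
  }
  hydro_groups <- c("FeFe_A1", "FeFe_A2", "FeFe_A3", "FeFe_B",
                    "NiFe_1", "NiFe_4a", "NiFe_4e", "Fe_only")
  cazy_fams <- sprintf("GH%02d", seq_len(n_cazy))
  substrate <- rep("plant cell wall", n_cazy)
  substrate[seq_len(n_animal)] <- "animal carbohydrates"
  substrate[n_animal + 5L + 1:3] <- "peptidoglycan"
  substrate[seq.int(n_cazy - 2L, n_cazy)] <- "other"
  names(substrate) <- cazy_fams

  with_seed(seed, {
    n <- length(samples)
    if (is.null(g)) g <- stats::rnorm(n)
    # coupled families are rare (base -1); five dominant stable families
    # (base 4, low noise) anchor the composition; the rest is background
    dom_c <- n_animal + seq_len(5L)
    base_c <- c(rep(-1, n_animal), rep(4, 5L),
                stats::rnorm(n_cazy - n_animal - 5L, 0, 0.8))
    sd_c <- rep(noise_sd, n_cazy); sd_c[dom_c] <- 0.15
    logc <- matrix(base_c, n, n_cazy, byrow = TRUE) +
      matrix(stats::rnorm(n * n_cazy), n) * matrix(sd_c, n, n_cazy, byrow = TRUE)
    coupled_fams <- cazy_fams[seq_len(n_animal)]
    logc[, seq_len(n_animal)] <- logc[, seq_len(n_animal)] + coupling * g
    nh <- length(hydro_groups)
    a3 <- match("FeFe_A3", hydro_groups)
    dom_h <- match(c("NiFe_1", "NiFe_4e", "Fe_only"), hydro_groups)
    base_h <- stats::rnorm(nh, 0, 0.8)
    base_h[a3] <- -1; base_h[dom_h] <- 4
    sd_h <- rep(noise_sd, nh); sd_h[dom_h] <- 0.15
    logh <- matrix(base_h, n, nh, byrow = TRUE) +
      matrix(stats::rnorm(n * nh), n) * matrix(sd_h, n, nh, byrow = TRUE)
    logh[, a3] <- logh[, a3] + coupling * g
    if (!is.null(severe))
      logh[, a3] <- logh[, a3] + severity_shift * as.numeric(severe)
    cazy <- exp(logc); cazy <- cazy / rowSums(cazy)
    hydro <- exp(logh); hydro <- hydro / rowSums(hydro)
    dimnames(cazy) <- list(samples, cazy_fams)
    dimnames(hydro) <- list(samples, hydro_groups)

    # gene-level view: 3 genes per family, counts from a fixed read depth
    mk_genes <- function(tab, prefix) {
      fams <- colnames(tab)
      genes <- as.vector(t(outer(fams, 1:3, function(f, i) sprintf("%s_g%d", f, i))))
      w <- stats::rgamma(length(genes), 2)
      cnt <- matrix(0, length(genes), nrow(tab), dimnames = list(genes, rownames(tab)))
      for (j in seq_along(fams)) {
        rows <- (j - 1L) * 3L + 1:3
        share <- w[rows] / sum(w[rows])
        cnt[rows, ] <- outer(share, tab[, j] * 1e5)
      }
      list(counts = round(cnt),
           map = data.frame(gene = genes, family = rep(fams, each = 3L)))
    }
    gc <- mk_genes(cazy, "cazy"); gh <- mk_genes(hydro, "hydro")
    gene_map <- rbind(cbind(gc$map, universe = "cazy"),
                      cbind(gh$map, universe = "hydrogenase"))
    planted <- data.frame(hydro = "FeFe_A3", cazy = coupled_fams)
    list(cazy = cazy, hydro = hydro, substrate_map = substrate,
         gene_counts = rbind(gc$counts, gh$counts), gene_map = gene_map,
         truth = list(planted_edges = planted, gas = g,
                      coupled_hydro = "FeFe_A3", coupled_cazy = coupled_fams))
  })
}

#' Write synthetic inputs as delimited text files
#'
#' Materialises a generated cohort in the package's interchange formats:
#' tab-separated tables for the food DB, diaries, clinical data and truth
#' latents; a dense genes-by-samples matrix; two-column mapping files for
#' the MSP catalog and functional annotations.
#'
#' @param sim list with any of `food_db`, `diary`, `clinical`, `counts`,
#'   `catalog`, `gene_map`, `truth`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_synthetic_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wt <- function(x, f, rn = FALSE) {
    p <- file.path(dir, f)
    utils::write.table(x, p, sep = "\t", quote = FALSE,
                       row.names = rn, col.names = TRUE)
    files <<- c(files, p)
  }
  if (!is.null(sim$food_db)) wt(sim$food_db, "food_db.tsv")
  if (!is.null(sim$diary)) wt(sim$diary, "diaries.tsv")
  if (!is.null(sim$clinical)) wt(sim$clinical, "clinical.tsv")
  if (!is.null(sim$counts)) wt(as.data.frame(sim$counts), "gene_counts.tsv", rn = TRUE)
  if (!is.null(sim$catalog)) {
    cat_df <- do.call(rbind, lapply(names(sim$catalog), function(m) {
      cg <- sim$catalog[[m]]
      data.frame(gene = c(cg$core, cg$accessory), msp = m,
                 role = c(rep("core", length(cg$core)),
                          rep("accessory", length(cg$accessory))))
    }))
    wt(cat_df, "msp_catalog.tsv")
  }
  if (!is.null(sim$gene_map)) wt(sim$gene_map, "gene_annotations.tsv")
  if (!is.null(sim$truth) && !is.null(sim$truth$subject_latents))
    wt(sim$truth$subject_latents, "truth_latents.tsv")
  invisible(files)
}
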