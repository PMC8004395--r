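# End-to-end orchestration: a single config drives synthetic generation (or
# file inputs), the diet stage (food tree, UniFrac, FSA-NPS), the MSP
# subspecies stage, diet-metagenome coupling (co-inertia + regression) and
# the functional stage (CAZotypes, network, LDA). Every threshold default
# is the pipeline's reference value: detection median coverage 2, accessory
# band 2.5-97.5%, silhouette floor 0.25, |rho| 0.4, 7 co-inertia axes,
# regression on 5 axes, 800/4500 kcal energy cutoffs.

#' Build a pipeline configuration
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param synthetic list of generator sizes (`n_items`, `n_nutrients`,
#'   `n_subjects`, `gradient_sd`, `n_msp`, `subspecies_spec`, `coupling`,
#'   `n_function_samples`); set to `NULL` when `inputs` paths are given.
#' @param inputs optional named list of input file paths (see
#'   [validate_inputs()]).
#' @param stages named logical list toggling `diet`, `msp`, `coupling`,
#'   `functions`.
#' @param thresholds named list: `detection`, `band` (length 2),
#'   `silhouette_floor`, `rho`, `n_axes`, `reg_k`, `energy_low`,
#'   `energy_high`, `pseudocount_g`, `train_frac`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 42L,
                            synthetic = list(),
                            inputs = NULL,
                            stages = list(),
                            thresholds = list()) {
  syn_def <- list(n_items = 120L, n_nutrients = 8L, n_subjects = 60L,
                  gradient_sd = 1, n_msp = 10L,
                  subspecies_spec = list(c(25L, 25L), c(20L, 20L, 20L),
                                         c(25L, 25L), integer(0)),
                  coupling = 0.8, n_function_samples = NULL)
  thr_def <- list(detection = 2, band = c(0.025, 0.975),
                  silhouette_floor = 0.25, rho = 0.4, n_axes = 7L,
                  reg_k = 5L, energy_low = 800, energy_high = 4500,
                  pseudocount_g = 1, train_frac = 2 / 3,
                  dmm_k_range = 1:3, cazotype_k_range = 1:4,
                  k_max = 5L, n_boot = 100L, min_detected = 10L)
  stg_def <- list(diet = TRUE, msp = TRUE, coupling = TRUE, functions = TRUE)
  cfg <- list(seed = as.integer(seed),
              synthetic = if (is.null(inputs))
                utils::modifyList(syn_def, synthetic) else NULL,
              inputs = inputs,
              stages = utils::modifyList(stg_def, stages),
              thresholds = utils::modifyList(thr_def, thresholds))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Write / read a pipeline configuration (JSON round-trip)
#'
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @return `write_pipeline_config`: the path, invisibly;
#'   `read_pipeline_config`: the configuration.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$synthetic$subspecies_spec))
    raw$synthetic$subspecies_spec <-
      lapply(raw$synthetic$subspecies_spec, as.integer)
  cfg <- pipeline_config(seed = raw$seed,
                         synthetic = raw$synthetic %||% list(),
                         inputs = raw$inputs,
                         stages = as.list(raw$stages),
                         thresholds = as.list(raw$thresholds))
  if (is.null(raw$synthetic)) cfg$synthetic <- NULL
  cfg
}

#' Validate pipeline input files
#'
#' Schema and cross-reference checks for the delimited-text input formats:
#' required columns, duplicate ids, diary items resolvable in the food DB,
#' catalog genes present in the count matrix (warning), clinical subjects
#' known. Never throws: returns a report.
#'
#' @param paths named list/vector with any of `food_db`, `diaries`,
#'   `clinical`, `gene_counts`, `msp_catalog`, `gene_annotations`.
#' @return data.frame report: `input`, `level` (error/warning/ok),
#'   `message`. An empty-failure report has only "ok" rows.
#' @export
validate_inputs <- function(paths) {
  paths <- as.list(paths)
  rep <- list()
  note <- function(input, level, message)
    rep[[length(rep) + 1L]] <<- data.frame(input = input, level = level,
                                           message = message)
  rd <- function(p) utils::read.delim(p, stringsAsFactors = FALSE)
  tabs <- list()
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) {
      note(nm, "error", paste0("file not found: ", paths[[nm]]))
      next
    }
    tabs[[nm]] <- tryCatch(rd(paths[[nm]]), error = function(e) {
      note(nm, "error", conditionMessage(e)); NULL
    })
  }
  need <- list(food_db = c("item_id", "level2", "level3", "level4",
                           "energy_kcal"),
               diaries = c("subject", "day", "meal", "item_id", "grams"),
               clinical = c("subject", "severity_group"),
               msp_catalog = c("gene", "msp", "role"),
               gene_annotations = c("gene", "family"))
  for (nm in intersect(names(tabs), names(need))) {
    miss <- setdiff(need[[nm]], names(tabs[[nm]]))
    if (length(miss))
      note(nm, "error", paste("missing column(s):", paste(miss, collapse = ", ")))
    else note(nm, "ok", paste(nrow(tabs[[nm]]), "rows"))
  }
  if (!is.null(tabs$food_db) && anyDuplicated(tabs$food_db$item_id))
    note("food_db", "error", "duplicate item_id")
  if (!is.null(tabs$diaries) && !is.null(tabs$food_db)) {
    unknown <- setdiff(tabs$diaries$item_id, tabs$food_db$item_id)
    if (length(unknown))
      note("diaries", "error",
           paste("item(s) not in food_db:", paste(unknown, collapse = ", ")))
  }
  if (!is.null(tabs$clinical) && !is.null(tabs$diaries)) {
    unknown <- setdiff(tabs$clinical$subject, tabs$diaries$subject)
    if (length(unknown))
      note("clinical", "warning",
           paste("subject(s) without diary:", paste(unknown, collapse = ", ")))
  }
  if (!is.null(paths$gene_counts) && file.exists(paths$gene_counts)) {
    gc <- tryCatch(utils::read.delim(paths$gene_counts, row.names = 1L),
                   error = function(e) NULL)
    if (is.null(gc)) note("gene_counts", "error", "unreadable matrix")
    else {
      note("gene_counts", "ok", paste(nrow(gc), "genes x", ncol(gc), "samples"))
      if (!is.null(tabs$msp_catalog)) {
        absent <- setdiff(tabs$msp_catalog$gene, rownames(gc))
        if (length(absent))
          note("msp_catalog", "warning",
               paste(length(absent), "catalog gene(s) absent from the matrix"))
      }
    }
  }
  out <- do.call(rbind, rep)
  rownames(out) <- NULL
  out
}

#' Run the full diet-metagenome pipeline
#'
#' Executes the enabled stages in dependency order on synthetic or file
#' inputs and (optionally) writes every output table plus a manifest of
#' parameters and seeds. Rerunning with the same config reproduces the
#' outputs exactly.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param quiet suppress stage log messages (stderr).
#' @return list of stage results: `data` (inputs + truth when synthetic),
#'   `diet`, `msp`, `coupling`, `functions`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  thr <- config$thresholds
  say <- function(...) if (!quiet) message(sprintf(...))
  t_start <- proc.time()[["elapsed"]]
  res <- list(manifest = list(seed = config$seed,
                              thresholds = thr,
                              stages = config$stages,
                              started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))

  ## ---- data stage -------------------------------------------------------
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    say("stage data: generating synthetic cohort (n=%d)", syn$n_subjects)
    food_db <- gen_food_db(syn$n_items, syn$n_nutrients,
                           seed = child_seed(config$seed, 1))
    dia <- gen_diaries(food_db, syn$n_subjects, gradient_sd = syn$gradient_sd,
                       seed = child_seed(config$seed, 2))
    n_msp <- syn$n_msp
    spec <- rep_len(syn$subspecies_spec, n_msp)
    mg <- gen_msp_metagenome(syn$n_subjects, n_msp, spec,
                             seed = child_seed(config$seed, 3),
                             truth = dia$truth, coupling = syn$coupling)
    clinical <- gen_clinical(dia$truth, seed = child_seed(config$seed, 4))
    ft <- gen_function_tables(truth = mg$truth,
                              severe = clinical$severity_group == 4,
                              seed = child_seed(config$seed, 5))
    res$data <- list(food_db = food_db, diary = dia$diary, clinical = clinical,
                     counts = mg$counts, catalog = mg$catalog,
                     functions = ft, truth = mg$truth)
  } else {
    if (is.null(config$inputs)) stop("config has neither synthetic nor inputs")
    say("stage data: reading inputs")
    vr <- validate_inputs(config$inputs)
    if (any(vr$level == "error"))
      stop("stage data: invalid inputs:\n",
           paste(vr$message[vr$level == "error"], collapse = "\n"),
           call. = FALSE)
    inp <- config$inputs
    res$data <- list(
      food_db = utils::read.delim(inp$food_db),
      diary = utils::read.delim(inp$diaries),
      clinical = if (!is.null(inp$clinical)) utils::read.delim(inp$clinical),
      counts = if (!is.null(inp$gene_counts))
        as.matrix(utils::read.delim(inp$gene_counts, row.names = 1L)),
      catalog = if (!is.null(inp$msp_catalog))
        catalog_from_table(utils::read.delim(inp$msp_catalog)),
      functions = NULL, truth = NULL)
  }
  d <- res$data

  ## ---- diet stage -------------------------------------------------------
  if (isTRUE(config$stages$diet)) {
    say("stage diet: food tree, UniFrac, FSA-NPS")
    filt <- filter_implausible_energy(d$diary, d$food_db,
                                      lower = thr$energy_low,
                                      upper = thr$energy_high)
    diary <- filt$kept
    tree <- build_food_tree(d$food_db, dmm_k_range = thr$dmm_k_range,
                            seed = child_seed(config$seed, 6))
    unifrac <- unifrac_matrix(diary, tree)
    subjects <- rownames(unifrac)
    grids <- fsanps_default_grids()
    scores <- stats::setNames(vapply(seq_len(nrow(d$food_db)), function(i)
      fsanps_item_score(d$food_db[i, ], d$food_db$fruitveg_pct[i], grids),
      numeric(1)), d$food_db$item_id)
    classes <- stats::setNames(fsanps_class(scores, d$food_db$is_drink),
                               d$food_db$item_id)
    energy <- stats::setNames(d$food_db$energy_kcal, d$food_db$item_id)
    di <- vapply(subjects, function(s)
      fsanps_diet_index(diary[diary$subject == s, ], scores, energy),
      numeric(1))
    ratio <- vapply(subjects, function(s)
      meat_plant_log2ratio(diary, tree, thr$pseudocount_g, subject = s),
      numeric(1))
    meals <- meal_quality_profile(diary, classes)
    res$diet <- list(tree = tree, unifrac = unifrac, diet_index = di,
                     meat_plant_ratio = ratio, item_scores = scores,
                     item_classes = classes, meal_quality = meals,
                     energy_filter = filt$report, diary = diary)
  }

  ## ---- msp stage --------------------------------------------------------
  if (isTRUE(config$stages$msp)) {
    if (is.null(d$counts))
      stop("stage msp: no gene counts available", call. = FALSE)
    say("stage msp: detection, accessory calls, subspecies")
    core_ab <- msp_core_abundance(d$counts, d$catalog)
    calls <- call_subspecies(d$counts, d$catalog, k_max = thr$k_max,
                             n_boot = thr$n_boot,
                             seed = child_seed(config$seed, 7),
                             silhouette_floor = thr$silhouette_floor,
                             min_detected = thr$min_detected,
                             detection_threshold = thr$detection,
                             q = thr$band)
    sub_ab <- subspecies_abundance(calls, core_ab)
    richness <- vapply(colnames(d$counts), function(s)
      gene_richness(d$counts, s), integer(1))
    res$msp <- list(core_abundance = core_ab, calls = calls,
                    subspecies_abundance = sub_ab, gene_richness = richness)
  }

  ## ---- coupling stage ---------------------------------------------------
  if (isTRUE(config$stages$coupling)) {
    if (is.null(res$diet) || is.null(res$msp))
      stop("stage coupling: requires the diet and msp stages", call. = FALSE)
    say("stage coupling: JSD, PCoA, co-inertia, regression")
    common <- intersect(rownames(res$diet$unifrac),
                        colnames(res$msp$subspecies_abundance))
    jsd <- jsd_distance(t(res$msp$subspecies_abundance[, common]))
    pc_diet <- pcoa(res$diet$unifrac[common, common])
    pc_mgs <- pcoa(jsd)
    nax <- function(p) max(2L, which(cumsum(p$var_fraction) >= 0.5)[1])
    kd <- nax(pc_diet); km <- nax(pc_mgs)
    with_seed(child_seed(config$seed, 8), {
      n <- length(common)
      train <- sort(sample.int(n, max(4L, floor(thr$train_frac * n))))
    })
    test <- setdiff(seq_along(common), train)
    ci <- coinertia(pc_diet$coords[train, 1:kd, drop = FALSE],
                    pc_mgs$coords[train, 1:km, drop = FALSE],
                    n_axes = thr$n_axes)
    cl <- d$clinical[match(common, d$clinical$subject), ]
    gas_ratio <- log2((cl$h2 + 1) / (cl$ch4 + 1))
    feats <- data.frame(
      severity = cl$severity_group,
      h2_ch4_ratio = gas_ratio,
      bmi = cl$bmi, age = cl$age,
      gene_richness = res$msp$gene_richness[common],
      meat_plant_ratio = res$diet$meat_plant_ratio[common],
      diet_quality = res$diet$diet_index[common])
    k_reg <- min(thr$reg_k, ci$n_axes, length(train) - 2L)
    regs <- lapply(c(severity = "severity", h2_ch4_ratio = "h2_ch4_ratio",
                     meat_plant_ratio = "meat_plant_ratio"), function(v) {
      y <- feats[[v]]
      reg <- pc_regression(ci$x_scores, y[train], k = k_reg)
      test_coords <- project_single_block(
        ci, pc_diet$coords[test, 1:kd, drop = FALSE], "x")
      pr <- predict(reg, test_coords, y[test])
      list(train_r = reg$train_r, test_r = pr$r, test_p = pr$p, k = k_reg)
    })
    axcor <- axis_feature_correlations(feats[train, ], ci$x_scores)
    pmv <- permanova(res$diet$unifrac[common, common],
                     feats$meat_plant_ratio, n_perm = 199,
                     seed = child_seed(config$seed, 9))
    # taxonomic scan: MSP nodes + subspecies nodes
    node_ab <- rbind(res$msp$core_abundance[, common, drop = FALSE] *
                       t(vapply(rownames(res$msp$core_abundance), function(m)
                         as.numeric(common %in% calls_detected(res$msp$calls, m)),
                         numeric(length(common)))),
                     res$msp$subspecies_abundance[, common, drop = FALSE])
    parent <- c(stats::setNames(rep(NA_character_,
                                    nrow(res$msp$core_abundance)),
                                rownames(res$msp$core_abundance)),
                stats::setNames(sub("\\|.*$", "",
                                    rownames(res$msp$subspecies_abundance)),
                                rownames(res$msp$subspecies_abundance)))
    scan <- permanova_scan(res$diet$unifrac[common, common], t(node_ab),
                           parent, n_perm = 19,
                           seed = child_seed(config$seed, 10))
    res$coupling <- list(jsd = jsd, pcoa_diet = pc_diet, pcoa_mgs = pc_mgs,
                         coinertia = ci, regressions = regs,
                         axis_correlations = axcor, permanova = pmv,
                         scan = scan, train = common[train],
                         test = common[test], features = feats)
  }

  ## ---- functions stage --------------------------------------------------
  if (isTRUE(config$stages$functions)) {
    say("stage functions: CAZy/hydrogenase profiles")
    ftab <- d$functions
    if (is.null(ftab))
      stop("stage functions: no functional tables available", call. = FALSE)
    cazy <- aggregate_families(ftab$gene_counts, ftab$gene_map, "cazy")
    hydro <- aggregate_families(ftab$gene_counts, ftab$gene_map, "hydrogenase")
    cz <- cazotype_partition(cazy, k_range = thr$cazotype_k_range,
                             seed = child_seed(config$seed, 11))
    assoc <- if (!is.null(d$clinical) && cz$K > 1 &&
                 length(unique(d$clinical$enterotype)) > 1)
      cazotype_enterotype_assoc(cz$labels[d$clinical$subject],
                                d$clinical$enterotype)
    net <- correlation_network(cazy, hydro, threshold = thr$rho)
    lda <- if (!is.null(d$clinical)) {
      sev <- d$clinical$severity_group
      use <- sev %in% c(1L, 4L)
      if (sum(sev[use] == 4L) >= 5 && sum(sev[use] == 1L) >= 5)
        lda_scores(hydro[d$clinical$subject[use], , drop = FALSE],
                   ifelse(sev[use] == 4L, "severe", "control"),
                   positive_class = "severe")
    }
    res$functions <- list(cazy = cazy, hydro = hydro, cazotypes = cz,
                          enterotype_assoc = assoc, network = net,
                          lda = lda)
  }

  res$manifest$elapsed_s <- round(proc.time()[["elapsed"]] - t_start, 2)
  if (!is.null(out_dir)) write_pipeline_outputs(res, config, out_dir)
  say("pipeline finished in %.1f s", res$manifest$elapsed_s)
  invisible(res)
}

calls_detected <- function(calls, msp) calls[[msp]]$detected

catalog_from_table <- function(tab) {
  out <- lapply(split(tab, tab$msp), function(x)
    list(core = x$gene[x$role == "core"],
         accessory = x$gene[x$role == "accessory"]))
  out
}

write_pipeline_outputs <- function(res, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f, rn = FALSE)
    utils::write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = rn, col.names = TRUE)
  if (!is.null(res$diet)) {
    wt(as.data.frame(res$diet$unifrac), "unifrac.tsv", rn = TRUE)
    wt(data.frame(subject = names(res$diet$diet_index),
                  diet_index = res$diet$diet_index,
                  meat_plant_log2ratio = res$diet$meat_plant_ratio),
       "diet_summary.tsv")
    wt(res$diet$meal_quality, "meal_quality.tsv")
    export_food_tree_newick(res$diet$tree, file.path(out_dir, "food_tree.nwk"))
  }
  if (!is.null(res$msp)) {
    wt(as.data.frame(res$msp$subspecies_abundance), "subspecies_abundance.tsv",
       rn = TRUE)
    part <- do.call(rbind, lapply(names(res$msp$calls), function(m) {
      p <- res$msp$calls[[m]]$partition
      if (is.null(p)) return(NULL)
      data.frame(msp = m, sample = names(p$labels),
                 subspecies = p$labels,
                 silhouette = max(p$silhouette),
                 stability = p$stability[p$labels])
    }))
    if (!is.null(part)) wt(part, "subspecies_partition.tsv")
  }
  if (!is.null(res$coupling)) {
    wt(as.data.frame(res$coupling$coinertia$x_scores), "coinertia_diet.tsv",
       rn = TRUE)
    wt(as.data.frame(res$coupling$coinertia$y_scores), "coinertia_mgs.tsv",
       rn = TRUE)
    wt(res$coupling$axis_correlations, "axis_correlations.tsv")
    wt(res$coupling$scan$table, "permanova_scan.tsv")
    regs <- do.call(rbind, lapply(names(res$coupling$regressions), function(v) {
      r <- res$coupling$regressions[[v]]
      data.frame(response = v, k = r$k, train_r = r$train_r,
                 test_r = r$test_r, test_p = r$test_p)
    }))
    wt(regs, "regressions.tsv")
  }
  if (!is.null(res$functions)) {
    wt(res$functions$network$edges, "network_edges.tsv")
    if (!is.null(res$functions$lda)) wt(res$functions$lda, "lda_scores.tsv")
    wt(data.frame(sample = names(res$functions$cazotypes$labels),
                  cazotype = res$functions$cazotypes$labels), "cazotypes.tsv")
  }
  manifest <- res$manifest
  manifest$config <- unclass(config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(out_dir)
}

#' Run the synthetic demo pipeline
#'
#' All-synthetic end-to-end run (default 60 subjects), the smoke-test entry
#' point also exposed by the `dietmg` command-line script.
#'
#' @param seed master seed.
#' @param n_subjects cohort size.
#' @param out_dir optional output directory.
#' @param quiet suppress stage messages.
#' @return pipeline result list (see [run_pipeline()]).
#' @export
demo_pipeline <- function(seed = 42L, n_subjects = 60L, out_dir = NULL,
                          quiet = FALSE) {
  cfg <- pipeline_config(seed = seed,
                         synthetic = list(n_subjects = as.integer(n_subjects)))
  run_pipeline(cfg, out_dir = out_dir, quiet = quiet)
}
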