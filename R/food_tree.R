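# Nutrient-informed hierarchical food tree and UniFrac diet distances.
#
# The tree has five internal levels: root (1), five broad categories (2:
# animal-based, plant-based, alcohol, fats, others), the food database
# hierarchy (3-4), and nutrient-based subcategories (5) obtained by fitting
# a Dirichlet multinomial mixture to each level-4 category's nutrient
# compositions. Leaves are food items. Unweighted UniFrac between two diet
# diaries is the branch length unique to either diary's consumed leaves
# over the total branch length they jointly touch.

.level2_classes <- c("animal-based", "plant-based", "alcohol", "fats", "others")

#' Build the 5-level nutrient-informed food tree
#'
#' Every level-4 category with at least two items has its per-100 g
#' nutrient compositions integerised (x10, rounded) and split by
#' [fit_dmm()]; each mixture component becomes a level-5 subcategory.
#' Singleton categories yield a single level-5 node.
#'
#' @param food_db food composition table with `item_id`, `level2`-`level4`
#'   and nutrient columns (see [gen_food_db()] for the expected layout).
#' @param level2_map optional named character vector mapping level-3 labels
#'   to level-2 classes, overriding `food_db$level2`.
#' @param dmm_k_range candidate component numbers for the per-category DMM.
#' @param seed integer seed (DMM initialisation).
#' @param branch_length common branch length (> 0); the unweighted metric
#'   only depends on topology, so this is a display/export convenience.
#' @return object of class `food_tree`: `items` (item table with the
#'   assigned `level5`), `nodes` (qualified internal node ids), `incidence`
#'   (leaf x node 0/1 matrix), `branch_length`, `n_level5`.
#' @export
build_food_tree <- function(food_db, level2_map = NULL, dmm_k_range = 1:3,
                            seed = 1L, branch_length = 1) {
  stopifnot(branch_length > 0)
  db <- as.data.frame(food_db)
  if (!is.null(level2_map)) db$level2 <- unname(level2_map[db$level3])
  bad <- is.na(db$level2) | !db$level2 %in% .level2_classes
  if (any(bad))
    stop("items with missing/unknown level-2 class: ",
         paste(db$item_id[bad], collapse = ", "), call. = FALSE)
  need <- c("item_id", "level3", "level4")
  if (!all(need %in% names(db)))
    stop("food_db must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  nutr_cols <- food_db_nutrient_cols(db)

  db$level5 <- NA_character_
  for (l4 in unique(db$level4)) {
    rows <- which(db$level4 == l4)
    if (length(rows) < 2) {
      db$level5[rows] <- paste0(l4, "_n1")
      next
    }
    x <- round(as.matrix(db[rows, nutr_cols, drop = FALSE]) * 10)
    # guard all-zero compositions (e.g. water-like drinks)
    zr <- rowSums(x) == 0
    if (any(zr)) x[zr, 1] <- 1L
    kr <- dmm_k_range[dmm_k_range <= length(rows)]
    if (length(kr) == 0) kr <- 1L
    fit <- suppressWarnings(fit_dmm(x, k_range = kr, seed = child_seed(seed, rows[1])))
    db$level5[rows] <- paste0(l4, "_n", fit$assignments)
  }

  qual <- function(...) paste(..., sep = "|")
  items <- db
  items$node2 <- qual("l2", items$level2)
  items$node3 <- qual("l3", items$level2, items$level3)
  items$node4 <- qual("l4", items$level2, items$level3, items$level4)
  items$node5 <- qual("l5", items$level2, items$level3, items$level4, items$level5)
  nodes <- unique(c(items$node2, items$node3, items$node4, items$node5))
  all_cols <- c(nodes, items$item_id)
  inc <- matrix(0L, nrow(items), length(all_cols),
                dimnames = list(items$item_id, all_cols))
  inc[cbind(seq_len(nrow(items)), match(items$node2, all_cols))] <- 1L
  inc[cbind(seq_len(nrow(items)), match(items$node3, all_cols))] <- 1L
  inc[cbind(seq_len(nrow(items)), match(items$node4, all_cols))] <- 1L
  inc[cbind(seq_len(nrow(items)), match(items$node5, all_cols))] <- 1L
  inc[cbind(seq_len(nrow(items)), match(items$item_id, all_cols))] <- 1L
  structure(list(items = items, nodes = nodes, incidence = inc,
                 branch_length = branch_length,
                 n_level5 = length(unique(items$node5))),
            class = "food_tree")
}

#' @export
print.food_tree <- function(x, ...) {
  cat("food_tree:", nrow(x$items), "items,",
      length(unique(x$items$level4)), "level-4 categories,",
      x$n_level5, "level-5 nutrient subcategories\n")
  invisible(x)
}

#' Binary diet presence profile on the food-tree leaves
#'
#' An item is present if it was consumed at least once (any grams > 0)
#' during the recorded days.
#'
#' @param diary diary table with `subject`, `item_id`, `grams`.
#' @param tree a `food_tree`.
#' @param subject subject id; defaults to the only subject in `diary`.
#' @return object of class `diet_profile`: subject plus a named logical
#'   presence vector over all leaves.
#' @export
diet_profile <- function(diary, tree, subject = NULL) {
  if (is.null(subject)) {
    subject <- unique(diary$subject)
    if (length(subject) != 1)
      stop("diary has several subjects; pass `subject`", call. = FALSE)
  }
  d <- diary[diary$subject == subject & diary$grams > 0, , drop = FALSE]
  unknown <- setdiff(d$item_id, tree$items$item_id)
  if (length(unknown))
    stop("items not on the tree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pres <- stats::setNames(tree$items$item_id %in% d$item_id,
                          tree$items$item_id)
  structure(list(subject = subject, presence = pres), class = "diet_profile")
}

profile_branch_vector <- function(p, tree) {
  if (inherits(p, "diet_profile")) p <- p$presence
  p <- p[tree$items$item_id]
  as.numeric(crossprod(tree$incidence, as.numeric(p)) > 0)
}

#' Unweighted UniFrac distance between two diet profiles
#'
#' Fraction of the observed branch length (root excluded) unique to one of
#' the two leaf-presence profiles: identical profiles give 0, profiles
#' sharing no branch below the root give 1.
#'
#' @param p,q `diet_profile` objects (or named logical presence vectors on
#'   the tree's leaves).
#' @param tree a `food_tree`.
#' @return numeric in \[0, 1\]; symmetric.
#' @export
unweighted_unifrac <- function(p, q, tree) {
  bp <- profile_branch_vector(p, tree)
  bq <- profile_branch_vector(q, tree)
  if (sum(bp) == 0 && sum(bq) == 0)
    stop("both profiles are empty", call. = FALSE)
  uniq <- sum(abs(bp - bq))
  tot <- sum(pmax(bp, bq))
  uniq / tot
}

#' Pairwise unweighted UniFrac matrix over a cohort of diaries
#'
#' @param diary diary table covering >= 2 subjects (duplicate subject ids
#'   within the table are aggregated; an explicitly duplicated subject id in
#'   `subjects` errors).
#' @param tree a `food_tree`.
#' @param subjects optional subject ordering.
#' @return symmetric `DistanceMatrix` with zero diagonal, entries in
#'   \[0, 1\], dimnames = subjects.
#' @export
unifrac_matrix <- function(diary, tree, subjects = NULL) {
  if (is.null(subjects)) subjects <- unique(diary$subject)
  if (anyDuplicated(subjects))
    stop("duplicate subject ids", call. = FALSE)
  if (length(subjects) < 2) stop("need >= 2 subjects", call. = FALSE)
  P <- vapply(subjects, function(s)
    profile_branch_vector(diet_profile(diary, tree, s), tree),
    numeric(ncol(tree$incidence)))
  A <- t(P)                                     # subjects x branches
  bl <- rep(tree$branch_length, ncol(A))
  S <- (A %*% (t(A) * bl))                      # shared branch length
  tot <- as.numeric(A %*% bl)
  U <- outer(tot, tot, `+`)
  D <- (U - 2 * S) / (U - S)
  D[U - S == 0] <- 0
  dimnames(D) <- list(subjects, subjects)
  diag(D) <- 0
  check_dist_matrix(D, "UniFrac matrix")
}

#' Log2 meat/plant ratio of a diary
#'
#' log2 of (grams of animal-based items + pseudocount) over (grams of
#' plant-based items + pseudocount); alcohol, fats and others contribute to
#' neither sum.
#'
#' @param diary diary table for one subject (or pass `subject`).
#' @param tree a `food_tree` (its item table supplies the level-2 classes).
#' @param pseudocount_g pseudocount in grams guarding empty categories.
#' @param subject optional subject filter.
#' @return numeric scalar.
#' @export
meat_plant_log2ratio <- function(diary, tree, pseudocount_g = 1,
                                 subject = NULL) {
  if (!is.null(subject)) diary <- diary[diary$subject == subject, , drop = FALSE]
  if (nrow(diary) == 0) stop("empty diary", call. = FALSE)
  lvl2 <- tree$items$level2[match(diary$item_id, tree$items$item_id)]
  if (anyNA(lvl2))
    stop("items not on the tree: ",
         paste(unique(diary$item_id[is.na(lvl2)]), collapse = ", "),
         call. = FALSE)
  animal <- sum(diary$grams[lvl2 == "animal-based"])
  plant <- sum(diary$grams[lvl2 == "plant-based"])
  log2((animal + pseudocount_g) / (plant + pseudocount_g))
}

#' Export a food tree in newick format
#'
#' Internal labels are sanitised level names; every branch gets the tree's
#' common branch length. The result parses with `ape::read.tree`.
#'
#' @param tree a `food_tree`.
#' @param path optional file to write to.
#' @return the newick string, invisibly when `path` is given.
#' @export
export_food_tree_newick <- function(tree, path = NULL) {
  it <- tree$items
  bl <- format(tree$branch_length)
  san <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)
  nest <- function(df, lvls) {
    if (length(lvls) == 0)
      return(paste0(san(df$item_id), ":", bl, collapse = ","))
    parts <- vapply(split(df, df[[lvls[1]]]), function(sub) {
      paste0("(", nest(sub, lvls[-1]), ")",
             san(sub[[lvls[1]]][1]), ":", bl)
    }, character(1))
    paste(parts, collapse = ",")
  }
  nwk <- paste0("(", nest(it, c("level2", "level3", "level4", "level5")),
                ")root;")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Convert a food tree to an ape phylo object
#'
#' @param x a `food_tree`.
#' @param ... unused.
#' @return an `ape::phylo`.
#' @export
as_phylo_food_tree <- function(x, ...) {
  ape::read.tree(text = export_food_tree_newick(x))
}
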