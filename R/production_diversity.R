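#' Farm production-diversity indices
#'
#' A farm's production is a long table with one row per farm and product:
#' `farm_id`, `product_id`, `value_usd` (annual monetary value of the
#' product), and the outlet split `frac_sold`, `frac_donated`,
#' `frac_selfconsumed` (summing to one per row).
#'
#' * `pdi()` - Production Diversity Index: count of distinct products
#'   (0/1 coding, so a token-value product counts fully).
#' * `sdi()` - Simpson Diversity Index on monetary value shares,
#'   `1 - sum(s_i^2)`.
#' * `gpdi()` - Group Production Diversity Index: count of distinct
#'   scorable MDD-W groups produced (0-10); unclassified products such as
#'   olive oil or garlic are excluded.
#' * `gsdi()` - Group Simpson Diversity Index: Simpson index on the
#'   monetary shares of the ten groups, with unclassified value excluded
#'   from both numerator and denominator.
#'
#' @param production Long production table (see above). `value_usd` is only
#'   required by the Simpson-type indices.
#' @return A tibble with `farm_id` and the index column.
#' @name production_indices_single
NULL

validate_production <- function(production, need_value = FALSE) {
  assert_cols(production, c("farm_id", "product_id"), "production table")
  catalogue <- product_catalogue()
  unknown <- setdiff(unique(production$product_id), catalogue$product_id)
  if (length(unknown) > 0) {
    abort(paste("unknown product_id(s):", paste(unknown, collapse = ", ")))
  }
  if (need_value) {
    assert_cols(production, "value_usd", "production table")
    if (any(production$value_usd < 0)) abort("value_usd must be >= 0")
  }
  invisible(production)
}

#' @rdname production_indices_single
#' @export
#' @examples
#' prod <- tibble::tibble(
#'   farm_id = "f1",
#'   product_id = c("wheat", "milk", "olive_oil"),
#'   value_usd = c(300, 500, 200),
#'   frac_sold = c(0.9, 0.2, 0.5), frac_donated = 0,
#'   frac_selfconsumed = c(0.1, 0.8, 0.5)
#' )
#' pdi(prod)
#' sdi(prod)
#' gpdi(prod)
pdi <- function(production) {
  validate_production(production)
  production |>
    dplyr::summarise(pdi = dplyr::n_distinct(.data$product_id),
                     .by = "farm_id")
}

simpson <- function(values) {
  1 - sum((values / sum(values))^2)
}

#' @rdname production_indices_single
#' @export
sdi <- function(production) {
  validate_production(production, need_value = TRUE)
  out <- production |>
    dplyr::summarise(total = sum(.data$value_usd),
                     sdi = simpson(.data$value_usd), .by = "farm_id")
  if (any(out$total <= 0)) {
    abort(sprintf("farm '%s' has zero total production value; SDI undefined",
                  out$farm_id[which(out$total <= 0)[1]]))
  }
  dplyr::select(out, "farm_id", "sdi")
}

join_groups <- function(production) {
  production |>
    dplyr::inner_join(product_catalogue()[, c("product_id", "group")],
                      by = "product_id")
}

#' @rdname production_indices_single
#' @export
gpdi <- function(production) {
  validate_production(production)
  join_groups(production) |>
    dplyr::summarise(
      gpdi = dplyr::n_distinct(.data$group[.data$group != "UNCLASSIFIED"]),
      .by = "farm_id")
}

#' @rdname production_indices_single
#' @export
gsdi <- function(production) {
  validate_production(production, need_value = TRUE)
  totals <- production |>
    dplyr::summarise(total = sum(.data$value_usd), .by = "farm_id")
  if (any(totals$total <= 0)) {
    abort(sprintf("farm '%s' has zero total production value",
                  totals$farm_id[which(totals$total <= 0)[1]]))
  }
  out <- join_groups(production) |>
    dplyr::filter(.data$group != "UNCLASSIFIED") |>
    dplyr::summarise(value = sum(.data$value_usd),
                     .by = c("farm_id", "group")) |>
    dplyr::summarise(scorable_total = sum(.data$value),
                     gsdi = simpson(.data$value), .by = "farm_id")
  missing <- setdiff(totals$farm_id, out$farm_id[out$scorable_total > 0])
  if (length(missing) > 0) {
    abort(sprintf(
      "farm '%s' has no production value in any scorable food group; GSDI undefined",
      missing[1]), class = "agridiet_no_scorable_production")
  }
  dplyr::select(out, "farm_id", "gsdi")
}

#' Standardize the product-nutrient matrix
#'
#' Divides each nutrient column by its daily reference intake for adult
#' women, then z-scores each column across products (mean 0, SD 1). This
#' is the substrate of the nutritional functional diversity dendrogram.
#'
#' @param nutrients Numeric matrix, products x nutrients.
#' @param rni Positive numeric vector of reference intakes, one per column.
#' @return A matrix of the same dimensions.
#' @export
standardize_nutrients <- function(nutrients, rni) {
  if (length(rni) != ncol(nutrients)) {
    abort("rni must have one entry per nutrient column")
  }
  if (any(rni <= 0)) abort("reference intakes must be strictly positive")
  scaled <- sweep(nutrients, 2, rni, "/")
  sds <- apply(scaled, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("nutrient column '%s' has zero variance across products",
                  colnames(nutrients)[which(sds == 0)[1]]))
  }
  scale(scaled, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

#' Pairwise Euclidean distances between products
#'
#' @param standardized Matrix from [standardize_nutrients()].
#' @return A symmetric matrix with zero diagonal.
#' @export
nutrient_distances <- function(standardized) {
  as.matrix(stats::dist(standardized, method = "euclidean"))
}

#' Build the product dendrogram
#'
#' Agglomeratively clusters the products from their pairwise nutrient
#' distances ([stats::hclust()]) and derives an ultrametric edge table
#' (leaf heights zero, node heights at half the merge distance, edge
#' length = parent height - child height; two leaves merged at distance
#' `d` are thus joined by a two-edge path of total length `d`). Ties
#' between merges are resolved by `hclust`'s deterministic ordering of the
#' input, so a given distance matrix always yields the same tree.
#'
#' @param distances Symmetric distance matrix (or `dist`).
#' @param method Linkage: `"average"` (default, UPGMA), `"single"`,
#'   `"complete"` or `"ward.D2"`.
#' @return An object of class `agridiet_dendrogram`: list with the
#'   `hclust` fit, `labels`, `edges` (tibble `parent`, `child`, `length`;
#'   leaves are nodes `1..n`, internal nodes `n+1..2n-1`, root `2n-1`),
#'   `heights`, and `total_branch_length`.
#' @export
build_dendrogram <- function(distances,
                             method = c("average", "single", "complete",
                                        "ward.D2")) {
  method <- match.arg(method)
  if (!inherits(distances, "dist")) {
    distances <- as.matrix(distances)
    if (!isSymmetric(unname(distances), tol = 1e-8)) {
      abort("distance matrix must be symmetric")
    }
    distances <- stats::as.dist(distances)
  }
  hc <- stats::hclust(distances, method = method)
  n <- length(hc$labels %||% hc$order)

  # node ids: leaves 1..n, internal node for merge i is n + i; heights are
  # half the merge distance so the path length between two leaves equals
  # their cophenetic distance (the standard ultrametric tree reading, and
  # the one ape uses when converting hclust trees)
  node_height <- c(rep(0, n), hc$height / 2)
  edges <- purrr::map_dfr(seq_len(nrow(hc$merge)), function(i) {
    parent <- n + i
    children <- ifelse(hc$merge[i, ] < 0, -hc$merge[i, ], n + hc$merge[i, ])
    tibble::tibble(parent = parent, child = as.integer(children),
                   length = node_height[parent] - node_height[children])
  })
  if (any(edges$length < -1e-8)) {
    abort("dendrogram is not ultrametric: merge heights decrease root-ward")
  }
  edges$length <- pmax(edges$length, 0)

  structure(
    list(hclust = hc, labels = hc$labels %||% as.character(seq_len(n)),
         n_leaves = n, edges = edges, heights = node_height,
         total_branch_length = sum(edges$length), method = method),
    class = "agridiet_dendrogram"
  )
}

#' @export
print.agridiet_dendrogram <- function(x, ...) {
  cat("Ultrametric product dendrogram (", x$method, " linkage)\n",
      "  leaves: ", x$n_leaves,
      "; total branch length: ", format(x$total_branch_length), "\n", sep = "")
  invisible(x)
}

#' Dendrogram from the bundled nutrient fixture
#'
#' Convenience wrapper chaining [load_nutrient_fixture()],
#' [standardize_nutrients()], [nutrient_distances()] and
#' [build_dendrogram()] with the default average linkage.
#'
#' @inheritParams build_dendrogram
#' @return An `agridiet_dendrogram` over the 29 reference products.
#' @export
reference_dendrogram <- function(method = "average") {
  key <- paste0("ref_dendro_", method)
  cached <- get0(key, envir = .agridiet_cache)
  if (!is.null(cached)) return(cached)
  fx <- load_nutrient_fixture()
  out <- build_dendrogram(nutrient_distances(standardize_nutrients(fx$nutrients,
                                                                   fx$rni)),
                          method = method)
  assign(key, out, envir = .agridiet_cache)
  out
}

.agridiet_cache <- new.env(parent = emptyenv())

#' Export a dendrogram as Newick
#'
#' @param dendro An `agridiet_dendrogram`.
#' @param path Optional file path; if omitted the Newick string is returned.
#' @return The Newick string, invisibly when written to `path`.
#' @export
as_newick <- function(dendro, path = NULL) {
  phy <- ape::as.phylo(dendro$hclust)
  if (is.null(path)) {
    return(ape::write.tree(phy))
  }
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

# For each edge, the set of leaves below it (list indexed like dendro$edges).
edge_leafsets <- function(dendro) {
  n <- dendro$n_leaves
  below <- vector("list", 2 * n - 1)
  for (i in seq_len(n)) below[[i]] <- i
  for (i in seq_len(nrow(dendro$hclust$merge))) {
    kids <- dendro$hclust$merge[i, ]
    ids <- ifelse(kids < 0, -kids, n + kids)
    below[[n + i]] <- c(below[[ids[1]]], below[[ids[2]]])
  }
  below
}

nfd_one <- function(leaf_idx, dendro, below, include_root_path) {
  sel <- leaf_idx
  keep <- vapply(seq_len(nrow(dendro$edges)), function(e) {
    b <- below[[dendro$edges$child[e]]]
    n_in <- sum(b %in% sel)
    if (include_root_path) {
      n_in >= 1
    } else {
      # minimal subtree spanning the selected leaves only: an edge is kept
      # iff some but not all selected leaves lie below it
      n_in >= 1 && n_in < length(sel)
    }
  }, logical(1))
  100 * sum(dendro$edges$length[keep]) / dendro$total_branch_length
}

#' Nutritional Functional Diversity score
#'
#' The NFD of a farm is the fraction (as a percentage, 0-100) of the
#' reference dendrogram's total branch length covered by the minimal
#' subtree connecting the farm's products. By default the subtree includes
#' the path up to the root, so a single-product farm scores more than zero
#' and adding a product can never lower the score; set
#' `include_root_path = FALSE` for the alternative convention that spans
#' only the selected leaves (a monoculture then scores 0).
#'
#' @param production Long production table, or a data frame with `farm_id`
#'   and `product_id` columns.
#' @param dendro An [build_dendrogram()] object whose labels cover all
#'   products present; defaults to [reference_dendrogram()].
#' @param include_root_path Include the path from the farm subtree to the
#'   root (default `TRUE`).
#' @return Tibble with `farm_id`, `nfd`.
#' @export
nfd <- function(production, dendro = NULL, include_root_path = TRUE) {
  validate_production(production)
  dendro <- dendro %||% reference_dendrogram()
  unknown <- setdiff(unique(production$product_id), dendro$labels)
  if (length(unknown) > 0) {
    abort(paste("product(s) not in dendrogram:",
                paste(unknown, collapse = ", ")))
  }
  below <- edge_leafsets(dendro)
  production |>
    dplyr::distinct(.data$farm_id, .data$product_id) |>
    dplyr::summarise(
      nfd = nfd_one(match(.data$product_id, dendro$labels), dendro, below,
                    include_root_path),
      .by = "farm_id")
}

#' Self-consumption share and farm orientation
#'
#' `self_consumption_share()` returns the monetary share of production
#' kept for home consumption (plus the sold and donated shares);
#' `classify_orientation()` labels each farm `SELF_CONSUMPTION` when more
#' than `threshold` (default 80%) of production value is kept,
#' `MARKET_ORIENTED` when more than `threshold` is sold, and `MIXED`
#' otherwise.
#'
#' @inheritParams production_indices_single
#' @param threshold Classification threshold on the value share (0.8).
#' @return A tibble keyed by `farm_id`.
#' @export
self_consumption_share <- function(production) {
  validate_production(production, need_value = TRUE)
  assert_cols(production, c("frac_sold", "frac_donated", "frac_selfconsumed"),
              "production table")
  bad <- abs(production$frac_sold + production$frac_donated +
               production$frac_selfconsumed - 1) > 1e-6
  if (any(bad)) {
    abort(sprintf("outlet fractions do not sum to 1 for farm '%s', product '%s'",
                  production$farm_id[which(bad)[1]],
                  production$product_id[which(bad)[1]]))
  }
  out <- production |>
    dplyr::summarise(
      total = sum(.data$value_usd),
      self_share = sum(.data$value_usd * .data$frac_selfconsumed) / sum(.data$value_usd),
      sold_share = sum(.data$value_usd * .data$frac_sold) / sum(.data$value_usd),
      donated_share = sum(.data$value_usd * .data$frac_donated) / sum(.data$value_usd),
      .by = "farm_id")
  if (any(out$total <= 0)) {
    abort(sprintf("farm '%s' has zero total production value",
                  out$farm_id[which(out$total <= 0)[1]]))
  }
  dplyr::select(out, -"total")
}

#' @rdname self_consumption_share
#' @export
classify_orientation <- function(production, threshold = 0.8) {
  self_consumption_share(production) |>
    dplyr::mutate(orientation = factor(
      dplyr::case_when(
        .data$self_share > threshold ~ "SELF_CONSUMPTION",
        .data$sold_share > threshold ~ "MARKET_ORIENTED",
        TRUE ~ "MIXED"
      ),
      levels = c("SELF_CONSUMPTION", "MARKET_ORIENTED", "MIXED"))) |>
    dplyr::select("farm_id", "orientation")
}

#' All production-diversity indices per farm
#'
#' One-stop scoring: PDI, SDI, GPDI, GSDI, NFD, self-consumption share and
#' orientation class for every farm in the production table.
#'
#' @inheritParams nfd
#' @inheritParams classify_orientation
#' @return A tibble with one row per farm.
#' @export
production_indices <- function(production, dendro = NULL,
                               include_root_path = TRUE, threshold = 0.8) {
  dendro <- dendro %||% reference_dendrogram()
  pdi(production) |>
    dplyr::left_join(sdi(production), by = "farm_id") |>
    dplyr::left_join(gpdi(production), by = "farm_id") |>
    dplyr::left_join(gsdi_safe(production), by = "farm_id") |>
    dplyr::left_join(nfd(production, dendro, include_root_path), by = "farm_id") |>
    dplyr::left_join(self_consumption_share(production), by = "farm_id") |>
    dplyr::left_join(classify_orientation(production, threshold), by = "farm_id")
}

# GSDI with NA (rather than an error) for farms with no scorable-group value,
# so whole-dataset scoring does not abort on all-unclassified farms.
gsdi_safe <- function(production) {
  scorable <- join_groups(production) |>
    dplyr::filter(.data$group != "UNCLASSIFIED")
  ok <- scorable |>
    dplyr::summarise(v = sum(.data$value_usd), .by = "farm_id") |>
    dplyr::filter(.data$v > 0)
  out <- production |> dplyr::distinct(.data$farm_id)
  if (nrow(ok) == 0) return(dplyr::mutate(out, gsdi = NA_real_))
  vals <- gsdi(dplyr::semi_join(production, ok, by = "farm_id"))
  dplyr::left_join(out, vals, by = "farm_id")
}
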