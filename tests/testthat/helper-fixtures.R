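# Builders used across the test files. All fixtures are generated in code.

GROUPS10 <- tolower(mddw_food_groups())

# One recall row; `consumed` is a character vector of lowercase group codes.
recall_row <- function(woman_id, season, consumed = character(),
                       olive_oil = 0) {
  vals <- as.list(setNames(as.integer(GROUPS10 %in% consumed), GROUPS10))
  tibble::tibble(woman_id = woman_id, season = season, !!!vals,
                 olive_oil = as.integer(olive_oil))
}

# Four-season recall set for one woman; `per_season` is a named list
# season -> character vector of groups.
make_recalls <- function(woman_id, per_season, olive_oil = 0) {
  purrr::map_dfr(c("autumn", "winter", "spring", "summer"), function(s) {
    recall_row(woman_id, s, per_season[[s]] %||% character(), olive_oil)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Long production table from a named list farm_id -> tibble(product_id,
# value, self, sold) or a plain character vector of products (value 1).
make_production <- function(products, values = NULL, self = 0, farm = "f1") {
  values <- values %||% rep(1, length(products))
  self <- rep(self, length.out = length(products))
  tibble::tibble(
    farm_id = farm, product_id = products, value_usd = values,
    frac_selfconsumed = self, frac_donated = 0, frac_sold = 1 - self)
}

# Deterministic 6-leaf toy dendrogram over real catalogue product ids.
toy_dendrogram <- function() {
  leaves <- c("wheat", "barley", "milk", "egg", "tomato", "grape")
  set.seed(4242)
  m <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(leaves, NULL))
  build_dendrogram(as.matrix(dist(m)))
}

# Independent NFD oracle: edge lengths of the union of leaf-to-root paths
# (root convention) or of the union of all pairwise leaf-to-leaf paths
# (leaf-spanning convention), found by explicit parent-pointer walks.
oracle_nfd <- function(dendro, leaf_labels, include_root_path = TRUE) {
  edges <- dendro$edges
  parent_of <- setNames(edges$parent, edges$child)
  root <- 2 * dendro$n_leaves - 1
  path_to_root <- function(node) {
    out <- integer(0)
    while (node != root) {
      out <- c(out, node)  # edge identified by its child node
      node <- parent_of[[as.character(node)]]
    }
    out
  }
  sel <- match(leaf_labels, dendro$labels)
  kept <- if (include_root_path) {
    unique(unlist(lapply(sel, path_to_root)))
  } else if (length(sel) == 1) {
    integer(0)
  } else {
    pairs <- utils::combn(sel, 2, simplify = FALSE)
    unique(unlist(lapply(pairs, function(p) {
      pa <- path_to_root(p[1])
      pb <- path_to_root(p[2])
      c(setdiff(pa, pb), setdiff(pb, pa))  # symmetric difference = path a-b
    })))
  }
  len <- sum(edges$length[match(kept, edges$child)])
  100 * len / dendro$total_branch_length
}

# Semantic table comparison tolerant to integer/double column coercion
# introduced by CSV round-trips.
expect_tables_equal <- function(a, b) {
  expect_equal(names(a), names(b))
  for (nm in names(a)) {
    x <- a[[nm]]; y <- b[[nm]]
    if (is.numeric(x) || is.numeric(y)) {
      expect_equal(as.numeric(x), as.numeric(y), tolerance = 1e-12)
    } else {
      expect_equal(as.character(x), as.character(y))
    }
  }
}
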