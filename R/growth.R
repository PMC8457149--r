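#' Per-tree annual diameter growth between consecutive censuses
#'
#' Growth over each consecutive census pair is
#' `(dbh2 - dbh1) / (date2 - date1)` in cm yr-1; negative growth is passed
#' through (filtering decides its fate later).
#'
#' @param census data.frame `tree_id`, `species`, `dbh_cm`, `date`
#'   (decimal years), `status` (`"alive"`/`"dead"`); dates strictly increasing
#'   within a tree.
#' @return data.frame `tree_id`, `species`, `interval` (1-based census pair
#'   index), `date_start`, `dbh_start`, `growth` (cm yr-1), `alive_both`.
#' @export
annual_growth <- function(census) {
  need <- c("tree_id", "species", "dbh_cm", "date", "status")
  if (!all(need %in% names(census))) stop("census table must have columns: ",
                                          paste(need, collapse = ", "))
  census <- census[order(census$tree_id, census$date), ]
  by_tree <- split(census, census$tree_id)
  rows <- lapply(by_tree, function(tr) {
    if (nrow(tr) < 2) return(NULL)
    dt <- diff(tr$date)
    if (any(dt <= 0)) stop("non-positive census interval for tree ", tr$tree_id[1])
    data.frame(tree_id = tr$tree_id[1], species = tr$species[1],
               interval = seq_len(nrow(tr) - 1),
               date_start = tr$date[-nrow(tr)],
               dbh_start = tr$dbh_cm[-nrow(tr)],
               growth = diff(tr$dbh_cm) / dt,
               alive_both = tr$status[-nrow(tr)] == "alive" &
                 tr$status[-1] == "alive",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter growth records to complete, large, canopy trees
#'
#' Keeps trees that (1) belong to species whose maximum height is at least
#' `min_height_m` (canopy species, fully sun-exposed), (2) entered the record
#' at `min_dbh` cm dbh or larger, (3) have a complete record: alive and
#' measured in every census interval present in the table, and (4) have no
#' growth record outside the outlier bounds (defaults -0.5 and 7.5 cm yr-1,
#' conventional large-plot census bounds). Trees violating any rule are
#' removed entirely; an empty result is allowed.
#'
#' @param growth table from [annual_growth()].
#' @param species_meta data.frame `species`, `max_height_m`.
#' @param min_dbh minimum dbh (cm) at the tree's first census.
#' @param min_height_m minimum species maximum height (m).
#' @param outlier_bounds length-2 numeric: allowed growth range, cm yr-1.
#' @return Filtered growth table (same columns).
#' @export
filter_trees <- function(growth, species_meta, min_dbh = 30,
                         min_height_m = 30, outlier_bounds = c(-0.5, 7.5)) {
  tall <- species_meta$species[species_meta$max_height_m >= min_height_m]
  g <- growth[growth$species %in% tall, , drop = FALSE]
  all_int <- sort(unique(growth$interval))
  keep <- vapply(split(g, g$tree_id), function(tr) {
    first <- tr$dbh_start[which.min(tr$interval)]
    first >= min_dbh &&
      length(setdiff(all_int, tr$interval)) == 0 &&
      all(tr$alive_both) &&
      all(tr$growth >= outlier_bounds[1] & tr$growth <= outlier_bounds[2])
  }, logical(1))
  out <- g[g$tree_id %in% names(keep)[keep], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Species growth series as median standardized size-model residuals
#'
#' Within each census interval, individual growth is regressed on
#' `ln(dbh at interval start)` pooled across species (the size model); the
#' residuals are z-scored within the interval (mean 0, variance 1); the
#' species value is the median residual of its trees. Species contributing
#' fewer than `min_trees` trees are dropped with a message.
#'
#' @param growth filtered table from [filter_trees()].
#' @param min_trees minimum complete trees per species.
#' @return data.frame `species`, `interval`, `g` (median standardized
#'   residual), `n_trees`.
#' @export
species_series <- function(growth, min_trees = 3) {
  if (nrow(growth) == 0) return(data.frame(species = character(),
                                           interval = integer(),
                                           g = numeric(), n_trees = integer()))
  counts <- table(unique(growth[, c("tree_id", "species")])$species)
  small <- names(counts)[counts < min_trees]
  if (length(small))
    message("dropping species below the ", min_trees, "-tree threshold: ",
            paste(small, collapse = ", "))
  g <- growth[!growth$species %in% small, , drop = FALSE]
  if (nrow(g) == 0) return(data.frame(species = character(),
                                      interval = integer(),
                                      g = numeric(), n_trees = integer()))
  rows <- lapply(split(g, g$interval), function(gi) {
    if (stats::var(log(gi$dbh_start)) > 0) {
      res <- stats::resid(stats::lm(growth ~ log(dbh_start), data = gi))
    } else {
      res <- gi$growth - mean(gi$growth)
    }
    tol <- 1e-10 * max(1, mean(abs(gi$growth)))
    z <- if (stats::sd(res) > tol) (res - mean(res)) / stats::sd(res) else res * 0
    med <- tapply(z, gi$species, stats::median)
    data.frame(species = names(med), interval = gi$interval[1],
               g = as.numeric(med),
               n_trees = as.integer(table(gi$species)[names(med)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$species, out$interval), ]
  rownames(out) <- NULL
  out
}
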