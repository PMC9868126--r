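#' Region sets: atlas-style hierarchy with volumes and exclusions
#'
#' A `region_set` is a validated data frame describing the brain regions a
#' count table refers to: one row per region with columns `id`, `acronym`,
#' `name`, `parent`, `anatomical_group`, `volume` (mm^3, per hemisphere) and
#' `excluded`. Acronyms are the join key used throughout the package; parent
#' links (by acronym, falling back to id) must form a forest.
#'
#' @param x data frame with columns `id`, `acronym`, `name`, `parent`,
#'   `anatomical_group`, `volume`.
#' @param exclude character vector of acronyms to flag as excluded (regions
#'   for which upstream cell detection failed); excluded regions are dropped
#'   before any statistics.
#' @return An object of class `region_set` (a data frame).
#' @examples
#' rs <- region_set(data.frame(
#'   id = 1:3, acronym = c("root", "A", "B"), name = c("Root", "A", "B"),
#'   parent = c(NA, "root", "root"), anatomical_group = "X",
#'   volume = c(1, 0.5, 0.25)))
#' @export
region_set <- function(x, exclude = NULL) {
  need <- c("id", "acronym", "name", "parent", "anatomical_group", "volume")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("region table is missing columns: ", paste(miss, collapse = ", "))
  x <- as.data.frame(x)[need]
  x$id <- as.character(x$id)
  x$acronym <- as.character(x$acronym)
  x$parent <- as.character(x$parent)
  x$parent[!is.na(x$parent) & x$parent == ""] <- NA_character_
  x$volume <- as.numeric(x$volume)

  if (anyDuplicated(x$id))
    stop("duplicate region ids: ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  if (anyDuplicated(x$acronym))
    stop("duplicate region acronyms: ",
         paste(unique(x$acronym[duplicated(x$acronym)]), collapse = ", "))
  if (any(!is.finite(x$volume)) || any(x$volume <= 0))
    stop("non-positive volume for region(s): ",
         paste(x$acronym[!is.finite(x$volume) | x$volume <= 0], collapse = ", "))

  x$excluded <- x$acronym %in% exclude
  if (!is.null(exclude)) {
    unknown <- setdiff(exclude, x$acronym)
    if (length(unknown))
      warning("exclusion list names absent regions: ",
              paste(unknown, collapse = ", "))
  }

  # parents resolve by acronym first, then id; links must form a forest
  has_parent <- !is.na(x$parent)
  pidx <- match(x$parent, x$acronym)
  alt <- match(x$parent, x$id)
  pidx[is.na(pidx)] <- alt[is.na(pidx)]
  orphan <- has_parent & is.na(pidx)
  if (any(orphan))
    stop("parent not found for region(s): ",
         paste(x$acronym[orphan], collapse = ", "))
  # cycle check by walking up from every node
  n <- nrow(x)
  for (i in seq_len(n)) {
    seen <- integer(0)
    j <- i
    while (!is.na(pidx[j])) {
      if (j %in% seen) stop("parent links contain a cycle at region ", x$acronym[i])
      seen <- c(seen, j)
      j <- pidx[j]
      if (length(seen) > n) stop("parent links contain a cycle")
    }
  }
  attr(x, "parent_index") <- pidx
  class(x) <- c("region_set", "data.frame")
  x
}

#' Read a region set from CSV
#'
#' @param path CSV file with header `id,acronym,name,parent,anatomical_group,volume`.
#' @param exclude either a character vector of acronyms or the path of a text
#'   file with one acronym per line.
#' @return A [region_set].
#' @export
read_region_set <- function(path, exclude = NULL) {
  if (is.character(exclude) && length(exclude) == 1 && file.exists(exclude))
    exclude <- readLines(exclude, warn = FALSE)
  exclude <- exclude[nzchar(exclude)]
  region_set(utils::read.csv(path, stringsAsFactors = FALSE), exclude = exclude)
}

#' @export
print.region_set <- function(x, n = 6, ...) {
  cat(sprintf("Region set: %d regions (%d excluded), %d anatomical groups, forest depth %d\n",
              nrow(x), sum(x$excluded), length(unique(x$anatomical_group)),
              max(region_depth(x))))
  print.data.frame(utils::head(x, n), ...)
  if (nrow(x) > n) cat("...", nrow(x) - n, "more regions\n")
  invisible(x)
}

#' Depth of each region in the parent forest (roots have depth 1)
#' @param regions a [region_set]
#' @return integer vector named by acronym
#' @export
region_depth <- function(regions) {
  pidx <- attr(regions, "parent_index")
  d <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    j <- i; k <- 1L
    while (!is.na(pidx[j])) { j <- pidx[j]; k <- k + 1L }
    d[i] <- k
  }
  names(d) <- regions$acronym
  d
}

#' Export a validated region set as JSON
#' @param regions a [region_set]
#' @param path output file
#' @export
write_region_set_json <- function(regions, path) {
  jsonlite::write_json(as.data.frame(regions), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Count tables: per-animal, per-region c-Fos-positive cell counts
#'
#' A `count_table` holds the non-negative integer counts of c-Fos-positive
#' cells for each animal (rows) and region (columns, named by acronym),
#' together with each animal's treatment-group label.
#'
#' @param counts numeric matrix, animals x regions, with animal row names and
#'   acronym column names; values must be non-negative integers.
#' @param group character or factor of group labels, one per animal (named by
#'   animal id, or in row order).
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer matrix) and `group` (named factor).
#' @export
count_table <- function(counts, group) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("animal", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    stop("count matrix must have region acronyms as column names")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  if (length(group) != nrow(counts))
    stop("one group label per animal is required")
  if (!is.null(names(group))) {
    if (!setequal(names(group), rownames(counts)))
      stop("group names do not match animal ids")
    group <- group[rownames(counts)]
  }
  group <- factor(as.character(group))
  names(group) <- rownames(counts)
  structure(list(counts = counts, group = group), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("Count table:", nrow(x$counts), "animals x", ncol(x$counts), "regions\n")
  print(table(x$group))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Read / write count tables as CSV
#'
#' The CSV dialect has one row per animal with `animal` and `group` columns
#' followed by one column per region acronym.
#'
#' @param path CSV file
#' @return A [count_table].
#' @export
read_count_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("animal", "group") %in% names(df)))
    stop("count CSV needs 'animal' and 'group' columns")
  m <- as.matrix(df[, setdiff(names(df), c("animal", "group")), drop = FALSE])
  rownames(m) <- df$animal
  count_table(m, stats::setNames(df$group, df$animal))
}

#' @rdname read_count_table
#' @param x a [count_table] (or density table)
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(animal = rownames(x$counts),
                   group = as.character(x$group),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(x$counts, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Convert counts to signal densities (cells per mm^3)
#'
#' Divides every count by the volume of its region. The conversion is exactly
#' invertible: multiplying densities by the volumes reconstructs the counts.
#'
#' @param x a [count_table]
#' @param regions a [region_set] providing volumes; every count column must be
#'   a non-excluded region of this set.
#' @return An object of class `density_table`: list with `values` (numeric
#'   matrix, cells/mm^3), `group`, and `volume` (named vector used).
#' @export
to_density <- function(x, regions) {
  stopifnot(inherits(x, "count_table"), inherits(regions, "region_set"))
  acr <- colnames(x$counts)
  missing <- setdiff(acr, regions$acronym)
  if (length(missing))
    stop("regions absent from region set: ", paste(missing, collapse = ", "))
  excl <- intersect(acr, regions$acronym[regions$excluded])
  if (length(excl))
    stop("excluded region(s) present in count table: ",
         paste(excl, collapse = ", "))
  vol <- stats::setNames(regions$volume, regions$acronym)[acr]
  structure(list(values = sweep(x$counts, 2, vol, `/`),
                 group = x$group, volume = vol),
            class = "density_table")
}

#' @export
print.density_table <- function(x, ...) {
  cat("Density table:", nrow(x$values), "animals x", ncol(x$values),
      "regions (cells/mm^3)\n")
  invisible(x)
}

#' Recover counts from a density table
#' @param x a `density_table`
#' @return A [count_table].
#' @export
from_density <- function(x) {
  stopifnot(inherits(x, "density_table"))
  counts <- round(sweep(x$values, 2, x$volume, `*`))
  count_table(counts, x$group)
}

#' Drop excluded regions from a count table
#' @param x a [count_table]
#' @param regions a [region_set]
#' @return A [count_table] without columns flagged excluded.
#' @export
drop_excluded <- function(x, regions) {
  keep <- setdiff(colnames(x$counts), regions$acronym[regions$excluded])
  count_table(x$counts[, keep, drop = FALSE], x$group)
}

#' Aggregate counts to ancestors at a fixed hierarchy level
#'
#' Counts of all regions lying below `level` in the parent forest are summed
#' into their ancestor at that level; aggregated volumes are the sums of the
#' contributing volumes, so density conversion stays consistent. Regions at or
#' above `level` pass through unchanged. Total counts are conserved.
#'
#' @param x a [count_table]
#' @param regions a [region_set] covering all count columns
#' @param level target depth (roots are depth 1)
#' @return list with `counts` (aggregated [count_table]) and `regions`
#'   (a [region_set] for the aggregated columns).
#' @export
aggregate_to_parents <- function(x, regions, level) {
  stopifnot(inherits(x, "count_table"), inherits(regions, "region_set"))
  if (level < 1) stop("level must be >= 1")
  depth <- region_depth(regions)
  if (level > max(depth)) stop("level exceeds forest depth ", max(depth))
  pidx <- attr(regions, "parent_index")
  # ancestor of each region at the target level (itself if depth <= level)
  anc <- seq_len(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    j <- i
    while (depth[j] > level && !is.na(pidx[j])) j <- pidx[j]
    anc[i] <- j
  }
  acr <- colnames(x$counts)
  ridx <- match(acr, regions$acronym)
  target <- regions$acronym[anc[ridx]]
  groups <- unique(target)
  agg <- sapply(groups, function(g)
    rowSums(x$counts[, target == g, drop = FALSE]))
  agg <- matrix(agg, nrow = nrow(x$counts),
                dimnames = list(rownames(x$counts), groups))
  vol <- tapply(regions$volume[ridx], target, sum)[groups]
  rdf <- as.data.frame(regions)[match(groups, regions$acronym), , drop = FALSE]
  rdf$volume <- as.numeric(vol)
  rdf$parent[!rdf$parent %in% groups] <- NA  # parents outside the slice
  new_rs <- region_set(rdf[, c("id", "acronym", "name", "parent",
                               "anatomical_group", "volume")],
                       exclude = rdf$acronym[rdf$excluded])
  list(counts = count_table(agg, x$group), regions = new_rs)
}
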