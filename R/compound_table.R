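#' Batch x compound concentration table
#'
#' Container for a batches x compounds concentration matrix (mg/g dry weight)
#' plus a compound -> class map. Classes are the four quantified families:
#' anthraquinone, stilbene_glycoside, flavonoid, phenol.
#'
#' @param concentrations numeric matrix, rows = batches, columns = compounds,
#'   with dimnames; no negative or missing cells.
#' @param compound_class named character vector mapping every compound to its
#'   class.
#' @param origin optional named character vector mapping batches to a region
#'   label.
#' @return an object of class `compound_table`.
#' @export
compound_table <- function(concentrations, compound_class, origin = NULL) {
  if (is.null(rownames(concentrations)) || is.null(colnames(concentrations)))
    .fail("concentration matrix must have batch and compound dimnames")
  if (anyDuplicated(rownames(concentrations)))
    .fail("duplicated batch id: %s",
          rownames(concentrations)[duplicated(rownames(concentrations))][1])
  na_cell <- which(is.na(concentrations), arr.ind = TRUE)
  if (nrow(na_cell <- as.matrix(na_cell)) > 0)
    .fail("missing concentration for batch %s, compound %s",
          rownames(concentrations)[na_cell[1, 1]],
          colnames(concentrations)[na_cell[1, 2]])
  neg <- which(concentrations < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    .fail("negative concentration for batch %s, compound %s",
          rownames(concentrations)[neg[1, 1]], colnames(concentrations)[neg[1, 2]])
  miss <- setdiff(colnames(concentrations), names(compound_class))
  if (length(miss))
    .fail("compound metadata missing for: %s", paste(miss, collapse = ", "))
  allowed <- c("anthraquinone", "stilbene_glycoside", "flavonoid", "phenol")
  bad <- setdiff(unique(compound_class), allowed)
  if (length(bad)) .fail("unknown compound class label: %s", paste(bad, collapse = ", "))
  structure(list(concentrations = concentrations,
                 compound_class = compound_class[colnames(concentrations)],
                 origin = origin),
            class = "compound_table")
}

#' @export
print.compound_table <- function(x, ...) {
  cat(sprintf("compound_table: %d batches x %d compounds (%s)\n",
              nrow(x$concentrations), ncol(x$concentrations),
              paste(sprintf("%d %s", table(x$compound_class)[unique(x$compound_class)],
                            unique(x$compound_class)), collapse = ", ")))
  invisible(x)
}

#' Read a compound table from CSV
#'
#' The data CSV holds one row per batch (first column = batch id) and one
#' numeric column per compound; the metadata CSV has columns
#' `compound, class` covering every data column. Rows with missing or
#' negative values are rejected with a batch/compound-level diagnostic.
#'
#' @param path data CSV path.
#' @param metadata_path metadata CSV path.
#' @param origin optional named character vector of batch origins.
#' @return a [compound_table()].
#' @export
read_compound_table <- function(path, metadata_path, origin = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) .fail("compound table needs a batch id column plus data")
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat)) .fail("non-numeric concentration cells in %s", path)
  rownames(mat) <- as.character(raw[[1]])
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  if (!all(c("compound", "class") %in% names(meta)))
    .fail("metadata must have columns 'compound' and 'class'")
  compound_table(mat, stats::setNames(meta$class, meta$compound), origin = origin)
}

#' Write a compound table (data + metadata CSVs)
#'
#' @param table a [compound_table()].
#' @param path data CSV path.
#' @param metadata_path metadata CSV path.
#' @return invisibly, `table`.
#' @export
write_compound_table <- function(table, path, metadata_path) {
  stopifnot(inherits(table, "compound_table"))
  df <- data.frame(batch_id = rownames(table$concentrations),
                   table$concentrations, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  utils::write.csv(data.frame(compound = names(table$compound_class),
                              class = unname(table$compound_class)),
                   metadata_path, row.names = FALSE)
  invisible(table)
}

#' Per-batch class totals and within-class compositional shares
#'
#' @param table a [compound_table()].
#' @return list with `totals` (batches x classes matrix of summed mg/g) and
#'   `shares` (per-class list of each compound's share of the class total,
#'   averaged over batches with a positive class total).
#' @export
class_totals <- function(table) {
  stopifnot(inherits(table, "compound_table"))
  classes <- unique(table$compound_class)
  conc <- table$concentrations
  totals <- sapply(classes, function(cl)
    rowSums(conc[, table$compound_class == cl, drop = FALSE]))
  if (is.null(dim(totals))) totals <- matrix(totals, nrow = 1,
                                             dimnames = list(rownames(conc), classes))
  shares <- lapply(stats::setNames(classes, classes), function(cl) {
    sub <- conc[, table$compound_class == cl, drop = FALSE]
    tot <- rowSums(sub)
    ok <- tot > 0
    if (!any(ok)) return(stats::setNames(rep(NA_real_, ncol(sub)), colnames(sub)))
    colMeans(sub[ok, , drop = FALSE] / tot[ok])
  })
  list(totals = totals, shares = shares)
}

#' Pharmacopoeial qualification of batches by THSG content
#'
#' A batch qualifies when its THSG concentration is at least the threshold
#' (default 10 mg/g = 1.0% w/w; "not less than" is inclusive, so the boundary
#' qualifies). Percent w/w converts as mg/g = 10 x percent.
#'
#' @param table a [compound_table()].
#' @param threshold_mg_per_g qualification threshold (default 10.0).
#' @param thsg_column name of the THSG column (default `"THSG"`).
#' @return data.frame with columns
#'   `batch_id, thsg_mg_per_g, threshold_mg_per_g, qualified`.
#' @export
qualify_batches <- function(table, threshold_mg_per_g = 10.0,
                            thsg_column = "THSG") {
  stopifnot(inherits(table, "compound_table"))
  if (!thsg_column %in% colnames(table$concentrations))
    .fail("column '%s' not present in the compound table", thsg_column)
  thsg <- table$concentrations[, thsg_column]
  data.frame(batch_id = rownames(table$concentrations),
             thsg_mg_per_g = unname(thsg),
             threshold_mg_per_g = threshold_mg_per_g,
             qualified = unname(thsg >= threshold_mg_per_g),
             stringsAsFactors = FALSE)
}
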