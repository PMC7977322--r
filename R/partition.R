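#' Partition breeding values by selection path
#'
#' Decomposes each individual's breeding value into a parent-average and
#' a Mendelian sampling term, and attributes it to selection paths by
#' recursing the pedigree from the oldest to the youngest individual:
#' half of each parent's partition vector flows to the offspring (a half
#' and a quarter for sire and maternal grandsire in `"sire-mgs"` mode)
#' and the Mendelian sampling term is credited to the individual's own
#' path. Founders' whole breeding values are credited to their own path.
#' Summed over paths, the partitions reconstruct the breeding value
#' exactly; averaged by year of birth they give partial genetic trends.
#'
#' An unknown parent contributes 0 to the parent average (the base
#' population is taken to have mean 0 after rebasing/standardisation),
#' so the missing half is absorbed into the Mendelian sampling term and
#' credited to the individual's own path -- continuous with the founder
#' rule.
#'
#' Multiple traits are carried through a single pedigree pass but
#' partitioned independently; columns of posterior samples of breeding
#' values can be passed the same way to propagate uncertainty.
#'
#' @param ped a [ped_table()] (or data.frame with canonical columns).
#'   It is topologically sorted internally for the recursion; result
#'   rows keep the input row order, so logical masks built against
#'   `ped` stay aligned with the trait tables.
#' @param path_column name of the categorical path column (defaults to
#'   the `path_column` attribute set by [read_pedigree()]).
#' @param trait_columns character vector of numeric breeding-value
#'   columns (defaults to the `trait_columns` attribute).
#' @param strict if `TRUE` (default) a missing path label is an error;
#'   if `FALSE` missing labels are bucketed into the literal path
#'   `"Unknown"` with a warning.
#' @return A `bv_partition`: a list with an `info` element
#'   (`path`, `nP`, `lP`, `nT`, `lT`, `warn`) and one data.frame per
#'   trait (named after the trait) holding all input columns plus
#'   `<trait>_pa`, `<trait>_w` and one `<trait>_<path>` column per path.
#' @examples
#' ped <- ped_table(data.frame(
#'   id = c("75165", "76300", "83134"), sire = c(NA, NA, "76300"),
#'   dam = c(NA, NA, "75165"), time = c(0, 0, 1),
#'   Population = c("Pop1", "Pop2", "Pop1"), Bv = c(9.20, 12.16, 10.42)))
#' p <- partition(ped, "Population", "Bv")
#' p$Bv[p$Bv$id == "83134", c("Bv_pa", "Bv_w", "Bv_Pop1", "Bv_Pop2")]
#' @export
partition <- function(ped, path_column = NULL, trait_columns = NULL,
                      strict = TRUE) {
  prep <- prepare_partition(ped, path_column, trait_columns, strict)
  kern <- .partition_kernel(prep$si, prep$di, prep$pathi, prep$bv,
                            length(prep$labels), prep$cSire, prep$cDam)
  out <- list(info = prep$info)
  for (t in seq_along(prep$traits)) {
    tr <- prep$traits[t]
    df <- as.data.frame(prep$ped_in)       # result rows keep the input order
    df[[paste0(tr, "_pa")]] <- kern$pa[prep$inv, t]
    df[[paste0(tr, "_w")]] <- kern$w[prep$inv, t]
    pm <- kern$parts[[t]][prep$inv, , drop = FALSE]
    colnames(pm) <- paste0(tr, "_", prep$labels)
    df <- cbind(df, as.data.frame(pm))
    out[[tr]] <- df
  }
  class(out) <- "bv_partition"
  out
}

## shared validation + index building for the recursive and matrix routes
prepare_partition <- function(ped, path_column, trait_columns, strict) {
  ped <- as_ped_table(ped)
  if (is.null(path_column)) path_column <- attr(ped, "path_column", exact = TRUE)
  if (is.null(trait_columns)) trait_columns <- attr(ped, "trait_columns", exact = TRUE)
  if (is.null(path_column)) stop("path_column must be given")
  if (is.null(trait_columns)) stop("trait_columns must be given")
  if (!path_column %in% names(ped)) {
    stop("path column '", path_column, "' not found")
  }
  miss <- setdiff(trait_columns, names(ped))
  if (length(miss) > 0L) {
    stop("trait column(s) not found: ", paste(miss, collapse = ", "))
  }
  ped_in <- ped
  ped <- validate_and_sort(ped)
  warn <- character(0)
  path <- as.character(ped[[path_column]])
  if (anyNA(path) || any(!nzchar(path))) {
    if (strict) {
      stop("missing path label(s) in column '", path_column,
           "' (use strict = FALSE to bucket them into path \"Unknown\")")
    }
    n_missing <- sum(is.na(path) | !nzchar(path))
    path[is.na(path) | !nzchar(path)] <- "Unknown"
    msg <- sprintf("%d record(s) with missing path label assigned to path \"Unknown\"",
                   n_missing)
    warning(msg)
    warn <- c(warn, msg)
  }
  bv <- as.matrix(as.data.frame(ped)[, trait_columns, drop = FALSE])
  if (!is.numeric(bv)) stop("trait columns must be numeric")
  storage.mode(bv) <- "double"
  labels <- sort(unique(path), method = "radix")
  coefs <- parent_coefficients(ped)
  list(ped = ped,
       ped_in = ped_in,
       inv = match(ped_in$id, ped$id),   # sorted row for each input row
       si = match(ped$sire, ped$id, nomatch = 0L),
       di = match(ped$dam, ped$id, nomatch = 0L),
       pathi = match(path, labels),
       bv = bv,
       labels = labels,
       traits = trait_columns,
       cSire = coefs[1L], cDam = coefs[2L],
       info = list(path = path_column, nP = length(labels), lP = labels,
                   nT = length(trait_columns), lT = trait_columns,
                   warn = warn))
}

## expected parental genome shares: sire-dam 1/2 + 1/2, sire-mgs 1/2 + 1/4
parent_coefficients <- function(ped) {
  switch(parent_mode(ped),
         "sire-dam" = c(0.5, 0.5),
         "sire-mgs" = c(0.5, 0.25))
}

#' @export
print.bv_partition <- function(x, ...) {
  cat(sprintf("Breeding-value partition: %d trait(s) [%s] x %d path(s) [%s] by '%s'\n",
              x$info$nT, paste(x$info$lT, collapse = ", "),
              x$info$nP, paste(x$info$lP, collapse = ", "), x$info$path))
  cat(sprintf("%d records per trait table\n", nrow(x[[x$info$lT[1L]]])))
  if (length(x$info$warn) > 0L) {
    cat("warnings:", paste(x$info$warn, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Partition and summarize in one pedigree pass
#'
#' Computes the same path partitions as [partition()] but accumulates
#' per-group totals on the fly and returns only group-level means,
#' never materialising the per-individual partition columns in the
#' result -- a useful speed-up for very large pedigrees. The result is
#' identical to `summarize_partition(partition(...), by, mean)`.
#'
#' @inheritParams partition
#' @param by name of the grouping column (e.g. year of birth).
#' @return A `bv_partition_summary` (see [summarize_partition()]), with
#'   mean aggregation.
#' @export
partition_and_summarize <- function(ped, path_column = NULL,
                                    trait_columns = NULL, by,
                                    strict = TRUE) {
  prep <- prepare_partition(ped, path_column, trait_columns, strict)
  if (!by %in% names(prep$ped)) stop("grouping column '", by, "' not found")
  keys <- as.character(prep$ped[[by]])
  lev <- order_group_levels(keys)
  gi <- match(keys, lev)
  kern <- .partition_group_kernel(prep$si, prep$di, prep$pathi, prep$bv,
                                  length(prep$labels), prep$cSire, prep$cDam,
                                  gi, length(lev))
  out <- list(info = c(prep$info, list(by = by, fun = "mean")))
  for (t in seq_along(prep$traits)) {
    tr <- prep$traits[t]
    df <- data.frame(key = restore_key_type(lev),
                     N = as.integer(kern$n),
                     Sum = kern$sum_bv[[t]] / kern$n,
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df)[1L] <- by
    pm <- kern$sum_part[[t]] / kern$n
    colnames(pm) <- prep$labels
    df <- cbind(df, as.data.frame(pm))
    out[[tr]] <- df
  }
  class(out) <- "bv_partition_summary"
  out
}

## ascending group order: numeric when every key parses as a number,
## lexicographic (C locale) otherwise
order_group_levels <- function(keys) {
  u <- unique(keys)
  num <- suppressWarnings(as.numeric(u))
  if (!anyNA(num)) u[order(num)] else sort(u, method = "radix")
}

restore_key_type <- function(lev) {
  num <- suppressWarnings(as.numeric(lev))
  if (!anyNA(num)) num else lev
}

#' Long-term genetic contributions of selection paths
#'
#' Partitions a constant unit "trait": every individual's breeding value
#' is set to 1, so the path partitions of an individual are the expected
#' fractions of its genome deriving from founders on each path. Rows are
#' non-negative and sum to one. These contributions are trait-agnostic;
#' they depend only on the pedigree and the path labelling.
#'
#' @inheritParams partition
#' @return A `bv_partition` for the synthetic trait `"contribution"`.
#' @export
long_term_contributions <- function(ped, path_column = NULL, strict = TRUE) {
  ped <- as_ped_table(ped)
  if ("contribution" %in% names(ped)) {
    stop("pedigree already has a 'contribution' column")
  }
  ped$contribution <- 1.0
  partition(ped, path_column = path_column, trait_columns = "contribution",
            strict = strict)
}
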