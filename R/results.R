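#' Summarize partitioned breeding values by a grouping variable
#'
#' Aggregates the total breeding value and each path partition within
#' levels of a grouping variable (typically year or generation of
#' birth), yielding the genetic trend (`Sum`) and the partial genetic
#' trends (one column per path). The default aggregation is the mean;
#' any function mapping a numeric vector to a single number may be used,
#' though for non-mean functions `Sum` need not equal the sum of the
#' path columns any more (documented, not enforced). A logical `subset`
#' restricts the records entering the summary (e.g. one population's
#' individuals only); `N` counts the subsetted records per group.
#'
#' @param res a `bv_partition` from [partition()].
#' @param by name of the grouping column in the trait tables.
#' @param fun aggregation function (default `mean`).
#' @param subset optional logical vector aligned to the trait-table rows.
#' @return A `bv_partition_summary`: list with `info` (the partition
#'   info plus `by` and `fun`) and one data.frame per trait with columns
#'   `<by>`, `N`, `Sum`, then one column per path label, groups ordered
#'   ascending by key.
#' @export
summarize_partition <- function(res, by, fun = mean, subset = NULL) {
  stopifnot(inherits(res, "bv_partition"))
  fun_name <- deparse(substitute(fun))[1L]
  out <- list(info = c(res$info, list(by = by, fun = fun_name)))
  for (tr in res$info$lT) {
    df <- res[[tr]]
    if (!by %in% names(df)) stop("grouping column '", by, "' not found")
    mask <- subset
    if (is.null(mask)) mask <- rep.int(TRUE, nrow(df))
    if (!is.logical(mask) || length(mask) != nrow(df) || anyNA(mask)) {
      stop("subset must be a complete logical vector aligned to the records")
    }
    df <- df[mask, , drop = FALSE]
    if (nrow(df) == 0L) {
      warning("empty subset: summary for trait '", tr, "' has no rows")
    }
    cols <- c(tr, paste0(tr, "_", res$info$lP))
    keys <- as.character(df[[by]])
    lev <- order_group_levels(keys)
    gi <- factor(keys, levels = lev)
    agg <- lapply(cols, function(cl) {
      v <- tapply(df[[cl]], gi, function(z) {
        r <- fun(z)
        if (!is.numeric(r) || length(r) != 1L) {
          stop("aggregation function must return a single number")
        }
        r
      })
      as.numeric(v)
    })
    sm <- data.frame(key = restore_key_type(lev),
                     N = as.integer(tabulate(gi, nbins = length(lev))),
                     Sum = agg[[1L]],
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(sm)[1L] <- by
    for (k in seq_along(res$info$lP)) {
      sm[[res$info$lP[k]]] <- agg[[k + 1L]]
    }
    out[[tr]] <- sm
  }
  class(out) <- "bv_partition_summary"
  out
}

#' @rdname summarize_partition
#' @param object a `bv_partition`.
#' @param ... passed on to [summarize_partition()].
#' @export
summary.bv_partition <- function(object, by, fun = mean, subset = NULL, ...) {
  summarize_partition(object, by = by, fun = fun, subset = subset)
}

#' @export
print.bv_partition_summary <- function(x, ...) {
  cat(sprintf("Partition summary by '%s' (%s): %d trait(s), %d path(s) [%s]\n",
              x$info$by, x$info$fun, x$info$nT, x$info$nP,
              paste(x$info$lP, collapse = ", ")))
  for (tr in x$info$lT) {
    cat("\n$", tr, "\n", sep = "")
    print(x[[tr]], ...)
  }
  invisible(x)
}

part_cols <- function(obj, trait) {
  if (inherits(obj, "bv_partition")) paste0(trait, "_", obj$info$lP) else obj$info$lP
}

#' Keep only some selection paths
#'
#' Drops the partition columns of all paths not in `paths`, on either a
#' `bv_partition` or a `bv_partition_summary`. Breeding-value / `Sum`
#' columns are untouched, so the retained partitions no longer sum to
#' the total; the `info$partial` flag records this.
#'
#' @param obj a `bv_partition` or `bv_partition_summary`.
#' @param paths character vector of path labels to keep.
#' @return Object of the same class with only the named paths.
#' @export
subset_paths <- function(obj, paths) {
  stopifnot(inherits(obj, c("bv_partition", "bv_partition_summary")))
  if (length(paths) == 0L) {
    stop("no paths to keep; known paths: ", paste(obj$info$lP, collapse = ", "))
  }
  unknown <- setdiff(paths, obj$info$lP)
  if (length(unknown) > 0L) {
    stop("unknown path(s): ", paste(unknown, collapse = ", "),
         "; known paths: ", paste(obj$info$lP, collapse = ", "))
  }
  keep <- obj$info$lP[obj$info$lP %in% paths]  # original order
  for (tr in obj$info$lT) {
    drop_cols <- setdiff(part_cols(obj, tr), part_cols_for(obj, tr, keep))
    obj[[tr]] <- obj[[tr]][, setdiff(names(obj[[tr]]), drop_cols), drop = FALSE]
  }
  if (length(keep) < length(obj$info$lP)) obj$info$partial <- TRUE
  obj$info$lP <- keep
  obj$info$nP <- length(keep)
  obj
}

part_cols_for <- function(obj, trait, labels) {
  if (inherits(obj, "bv_partition")) paste0(trait, "_", labels) else labels
}

#' Combine selection paths
#'
#' Sums the partition columns of named constituent paths into new
#' combined paths, e.g. merging two imported populations into a single
#' `Import` path. Each mapping element is `new_label = c(constituents)`;
#' a singleton mapping renames a path. Paths not mentioned are kept
#' unchanged (and precede the combined paths in the result). The total
#' over all partition columns is preserved exactly.
#'
#' @param obj a `bv_partition` or `bv_partition_summary`.
#' @param mapping named list: new path label -> character vector of
#'   constituent path labels. A constituent may appear in at most one
#'   element.
#' @return Object of the same class with combined paths.
#' @examples \dontrun{
#' combine_paths(sm, list(Domestic = "Pop1", Import = c("Pop2", "Pop3")))
#' }
#' @export
combine_paths <- function(obj, mapping) {
  stopifnot(inherits(obj, c("bv_partition", "bv_partition_summary")))
  if (length(mapping) == 0L) return(obj)
  new_labels <- names(mapping)
  if (is.null(new_labels) || any(!nzchar(new_labels))) {
    stop("every mapping element must be named by the new path label")
  }
  if (anyDuplicated(new_labels)) {
    stop("duplicate new path label(s): ",
         paste(unique(new_labels[duplicated(new_labels)]), collapse = ", "))
  }
  constituents <- unlist(mapping, use.names = FALSE)
  unknown <- setdiff(constituents, obj$info$lP)
  if (length(unknown) > 0L) {
    stop("unknown constituent path(s): ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(constituents)) {
    stop("constituent path(s) appear in more than one group: ",
         paste(unique(constituents[duplicated(constituents)]), collapse = ", "))
  }
  untouched <- setdiff(obj$info$lP, constituents)
  clash <- intersect(new_labels, untouched)
  if (length(clash) > 0L) {
    stop("new label(s) collide with kept path(s): ", paste(clash, collapse = ", "))
  }
  for (tr in obj$info$lT) {
    df <- obj[[tr]]
    add <- list()
    for (nl in new_labels) {
      src <- part_cols_for(obj, tr, mapping[[nl]])
      add[[part_cols_for(obj, tr, nl)]] <-
        if (length(src) == 1L) df[[src]] else rowSums(df[, src, drop = FALSE])
    }
    df <- df[, setdiff(names(df), part_cols_for(obj, tr, constituents)),
             drop = FALSE]
    for (cn in names(add)) df[[cn]] <- add[[cn]]
    obj[[tr]] <- df
  }
  obj$info$lP <- c(untouched, new_labels)
  obj$info$nP <- length(obj$info$lP)
  obj
}

#' Write / read partition results and summaries
#'
#' Serialises a `bv_partition` or `bv_partition_summary` as one CSV per
#' trait (`<prefix>.<trait>.csv`) plus a JSON metadata sidecar
#' (`<prefix>.info.json`) holding the info block and the object class,
#' so pipeline stages (including the command-line interface) can be
#' chained through plain files.
#'
#' @param obj object to write.
#' @param prefix output path prefix.
#' @return `write_partition_result`: the prefix, invisibly;
#'   `read_partition_result`: the reconstructed object.
#' @export
write_partition_result <- function(obj, prefix) {
  stopifnot(inherits(obj, c("bv_partition", "bv_partition_summary")))
  for (tr in obj$info$lT) {
    utils::write.csv(csv_ready(obj[[tr]]), paste0(prefix, ".", tr, ".csv"),
                     row.names = FALSE, quote = FALSE)
  }
  meta <- obj$info
  meta$class <- class(obj)[1L]
  jsonlite::write_json(meta, paste0(prefix, ".info.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_partition_result
#' @export
read_partition_result <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".info.json"),
                              simplifyVector = TRUE)
  cls <- meta$class
  meta$class <- NULL
  ## scalar lists back to plain vectors
  meta$lP <- as.character(meta$lP)
  meta$lT <- as.character(meta$lT)
  meta$warn <- as.character(meta$warn)
  obj <- list(info = meta)
  for (tr in meta$lT) {
    obj[[tr]] <- utils::read.csv(paste0(prefix, ".", tr, ".csv"),
                                 check.names = FALSE,
                                 stringsAsFactors = FALSE)
  }
  class(obj) <- cls
  obj
}
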