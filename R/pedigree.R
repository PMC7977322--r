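#' Pedigree tables
#'
#' A `ped_table` is a plain `data.frame` with four canonical columns --
#' `id`, `sire`, `dam` (character identifiers; `NA` marks an unknown
#' parent) and `time` (integer year or generation of birth, possibly `NA`
#' before repair) -- plus any number of extra columns such as a selection
#' path label and breeding-value columns. The `parent_mode` attribute
#' records whether the second parental column holds the dam
#' (`"sire-dam"`) or the maternal grandsire (`"sire-mgs"`); the expected
#' parental contributions used downstream are 1/2 + 1/2 and 1/2 + 1/4
#' respectively.
#'
#' In input files an unknown parent may be written as an empty string,
#' `"0"` or `NA`; all three normalise to the single internal sentinel
#' `NA`.
#'
#' @param df data.frame holding at least `id`, `sire`, `dam` and `time`
#'   columns (already under canonical names).
#' @param parent_mode `"sire-dam"` or `"sire-mgs"`.
#' @return A `ped_table` (data.frame subclass).
#' @seealso [read_pedigree()] to build one from a delimited file,
#'   [validate_and_sort()], [fix_birth_years()], [set_base()].
#' @export
ped_table <- function(df, parent_mode = c("sire-dam", "sire-mgs")) {
  parent_mode <- match.arg(parent_mode)
  stopifnot(is.data.frame(df))
  need <- c("id", "sire", "dam", "time")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("missing canonical pedigree column(s): ", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$id <- as.character(df$id)
  df$sire <- normalize_unknown(as.character(df$sire))
  df$dam <- normalize_unknown(as.character(df$dam))
  if (anyNA(df$id) || any(!nzchar(df$id))) {
    stop("id column has missing values")
  }
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup) > 0L) {
    stop("duplicate ids in pedigree: ", paste(utils::head(dup, 10L), collapse = ", "))
  }
  df$time <- check_integer_time(df$time)
  rownames(df) <- NULL
  structure(df,
            parent_mode = parent_mode,
            class = c("ped_table", "data.frame"))
}

#' @export
print.ped_table <- function(x, ...) {
  cat(sprintf("Pedigree table: %d individuals (%s mode)\n",
              nrow(x), parent_mode(x)))
  NextMethod()
  invisible(x)
}

#' Parental-column semantics of a pedigree
#'
#' @param ped a `ped_table`.
#' @return `"sire-dam"` or `"sire-mgs"`.
#' @export
parent_mode <- function(ped) {
  pm <- attr(ped, "parent_mode", exact = TRUE)
  if (is.null(pm)) "sire-dam" else pm
}

## empty string and "0" are common unknown-parent dialects in pedigree files
normalize_unknown <- function(x) {
  x[!is.na(x) & (x == "" | x == "0")] <- NA_character_
  x
}

check_integer_time <- function(time) {
  if (is.character(time)) {
    time2 <- suppressWarnings(as.numeric(time))
    bad <- !is.na(time) & nzchar(time) & is.na(time2)
    if (any(bad)) {
      stop("non-numeric time value(s), e.g. row ", which(bad)[1L])
    }
    time <- time2
  }
  time <- as.numeric(time)
  frac <- !is.na(time) & time != round(time)
  if (any(frac)) {
    stop("time must be integer-valued (year or generation of birth); ",
         "fractional value at row ", which(frac)[1L])
  }
  as.integer(round(time))
}

#' Read a pedigree from a delimited text file
#'
#' Reads a CSV (or TSV) file with a header row, renames the mapped columns
#' to the canonical names `id`, `sire`, `dam` and `time`, validates
#' identifiers and breeding-value columns, and normalises unknown-parent
#' codes (`""`, `"0"`, `NA`) to `NA`. Parent identifiers that never occur
#' in the `id` column are treated as unknown; the number of such dropped
#' links is kept in the `n_unknown_parent_links` attribute and reported
#' with a warning.
#'
#' @param source path to a delimited text file with a header.
#' @param column_map named list mapping canonical roles to file column
#'   names: `id`, `sire`, `dam` (required), `time`, `path` (optional) and
#'   `bv`, a character vector of breeding-value columns (optional).
#' @param mode parental semantics of the second parent column:
#'   `"sire-dam"` (default) or `"sire-mgs"` (maternal grandsire).
#' @param sep field separator, `","` by default (use `"\t"` for TSV).
#' @return A [ped_table()]. Mapped path / breeding-value columns keep
#'   their file names and are recorded in the `path_column` and
#'   `trait_columns` attributes.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("Generation,IId,FId,MId,Population,Bv",
#'              "0,75165,0,0,Pop1,9.20",
#'              "0,76300,0,0,Pop2,12.16",
#'              "1,83134,76300,75165,Pop1,10.42"), f)
#' ped <- read_pedigree(f, column_map = list(time = "Generation", id = "IId",
#'                                           sire = "FId", dam = "MId",
#'                                           path = "Population", bv = "Bv"))
#' @export
read_pedigree <- function(source, column_map, mode = c("sire-dam", "sire-mgs"),
                          sep = ",") {
  mode <- match.arg(mode)
  if (!file.exists(source)) stop("input file not found: ", source)
  df <- utils::read.table(source, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  for (role in c("id", "sire", "dam")) {
    if (is.null(column_map[[role]])) {
      stop("column_map must name the '", role, "' column")
    }
  }
  mapped <- c(column_map$id, column_map$sire, column_map$dam,
              column_map$time, column_map$path, column_map$bv)
  miss <- setdiff(mapped, names(df))
  if (length(miss) > 0L) {
    stop("mapped column(s) absent from file: ", paste(miss, collapse = ", "))
  }
  ren <- c(id = column_map$id, sire = column_map$sire, dam = column_map$dam)
  if (!is.null(column_map$time)) ren <- c(ren, time = column_map$time)
  names(df)[match(ren, names(df))] <- names(ren)
  if (is.null(column_map$time)) df$time <- NA_integer_
  for (bv in column_map$bv) {
    v <- suppressWarnings(as.numeric(df[[bv]]))
    bad <- is.na(v) & !is.na(df[[bv]]) & nzchar(df[[bv]])
    if (any(bad)) {
      stop("non-numeric breeding-value entry in column '", bv,
           "', row ", which(bad)[1L])
    }
    df[[bv]] <- v
  }
  ped <- ped_table(df, parent_mode = mode)
  ped <- drop_phantom_parents(ped)
  attr(ped, "path_column") <- column_map$path
  attr(ped, "trait_columns") <- column_map$bv
  ped
}

## parents never listed as individuals become UNKNOWN (counted + warned)
drop_phantom_parents <- function(ped) {
  known <- ped$id
  n_dropped <- 0L
  for (col in c("sire", "dam")) {
    phantom <- !is.na(ped[[col]]) & !(ped[[col]] %in% known)
    n_dropped <- n_dropped + sum(phantom)
    ped[[col]][phantom] <- NA_character_
  }
  attr(ped, "n_unknown_parent_links") <- n_dropped
  if (n_dropped > 0L) {
    warning(n_dropped, " parent link(s) referenced individuals absent from ",
            "the id column; treated as unknown parents")
  }
  ped
}

#' Write a pedigree to a delimited text file
#'
#' Inverse of [read_pedigree()] for canonical tables: unknown parents are
#' written as `"0"`.
#'
#' @param ped a `ped_table`.
#' @param path output file path.
#' @param sep field separator.
#' @export
write_pedigree <- function(ped, path, sep = ",") {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.table(csv_ready(out), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

## print doubles with enough digits to round-trip exactly through text
csv_ready <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- sprintf("%.17g", df[[j]])
      v[is.na(df[[j]])] <- "NA"
      df[[j]] <- v
    }
  }
  df
}

#' Topologically sort a pedigree, parents before offspring
#'
#' Orders records so that every parent precedes all of its offspring and
#' checks the pedigree is acyclic. The order is canonical -- ascending by
#' (generation depth, time, id), where depth is the length of the longest
#' known-ancestor chain -- so the result does not depend on the input row
#' order.
#'
#' @param ped a `ped_table` (or coercible data.frame).
#' @return The sorted `ped_table`.
#' @export
validate_and_sort <- function(ped) {
  ped <- as_ped_table(ped)
  n <- nrow(ped)
  if (n == 0L) return(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  depth <- rep.int(NA_integer_, n)
  ready <- is.na(si) & is.na(di)
  depth[ready] <- 0L
  repeat {
    sd <- depth[si]; dd <- depth[di]
    sd[is.na(si)] <- -1L; dd[is.na(di)] <- -1L
    cand <- is.na(depth) & (is.na(si) | !is.na(depth[si])) &
      (is.na(di) | !is.na(depth[di]))
    if (!any(cand)) break
    depth[cand] <- pmax(sd[cand], dd[cand]) + 1L
  }
  if (anyNA(depth)) {
    stop("pedigree contains a cycle involving: ",
         paste(find_cycle(ped$id, si, di, which(is.na(depth))), collapse = " -> "))
  }
  tkey <- ped$time
  tkey[is.na(tkey)] <- .Machine$integer.max  # unknown times sort last in ties
  ord <- order(depth, tkey, ped$id, method = "radix")
  out <- ped[ord, , drop = FALSE]
  rownames(out) <- NULL
  keep_ped_attrs(out, ped)
}

## walk parent links from an unresolved node until one repeats
find_cycle <- function(ids, si, di, unresolved) {
  start <- unresolved[1L]
  seen <- integer(0)
  cur <- start
  while (!(cur %in% seen)) {
    seen <- c(seen, cur)
    nxt <- c(si[cur], di[cur])
    nxt <- nxt[!is.na(nxt) & nxt %in% unresolved]
    if (length(nxt) == 0L) {  # unresolved only through the other parent
      nxt <- c(si[cur], di[cur]); nxt <- nxt[!is.na(nxt)]
    }
    cur <- nxt[1L]
  }
  cyc <- seen[which(seen == cur):length(seen)]
  ids[c(cyc, cur)]
}

keep_ped_attrs <- function(new, old) {
  for (a in c("parent_mode", "path_column", "trait_columns",
              "n_unknown_parent_links")) {
    attr(new, a) <- attr(old, a, exact = TRUE)
  }
  class(new) <- class(old)
  new
}

#' Coerce a data.frame to a pedigree table
#'
#' @param ped data.frame with canonical columns, or an existing `ped_table`.
#' @param parent_mode used only when `ped` is not yet a `ped_table`.
#' @return A `ped_table`.
#' @export
as_ped_table <- function(ped, parent_mode = c("sire-dam", "sire-mgs")) {
  if (inherits(ped, "ped_table")) return(ped)
  ped_table(ped, parent_mode = match.arg(parent_mode))
}

#' Impute missing birth years from relatives
#'
#' Fills missing values of the time variable using the generation
#' interval. With `down = FALSE` a parent's missing time is imputed from
#' its offspring as (time of the oldest offspring) - `interval`; with
#' `down = TRUE` an offspring's missing time is imputed from its parents
#' as (time of the youngest parent) + `interval`. Passes repeat until no
#' further value changes. Records that could not be imputed are reported
#' in the `not_imputed` attribute (and with a warning).
#'
#' Only imputation is performed: existing times are never altered and no
#' parent-older-than-offspring check is enforced here (see
#' [check_time_consistency()]).
#'
#' @param ped a `ped_table`.
#' @param interval positive integer generation interval, in time units.
#' @param down direction of imputation (see above).
#' @return The `ped_table` with imputed times.
#' @export
fix_birth_years <- function(ped, interval, down = FALSE) {
  ped <- as_ped_table(ped)
  if (!is.numeric(interval) || length(interval) != 1L || interval < 1 ||
      interval != round(interval)) {
    stop("interval must be a positive integer")
  }
  if (all(is.na(ped$time))) stop("all time values are missing; nothing to anchor on")
  interval <- as.integer(interval)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  time <- ped$time
  repeat {
    changed <- FALSE
    if (!down) {
      ## parent <- oldest (earliest-born) offspring - interval
      off_min <- rep.int(NA_integer_, nrow(ped))
      for (pi in list(si, di)) {
        has <- !is.na(pi) & !is.na(time)
        if (any(has)) {
          m <- tapply(time[has], pi[has], min)
          idx <- as.integer(names(m))
          off_min[idx] <- pmin(off_min[idx], as.integer(m), na.rm = TRUE)
        }
      }
      fill <- is.na(time) & !is.na(off_min)
      if (any(fill)) {
        time[fill] <- off_min[fill] - interval
        changed <- TRUE
      }
    } else {
      ## offspring <- youngest (latest-born) parent + interval
      pmaxt <- pmax(ifelse(is.na(si), NA_integer_, time[si]),
                    ifelse(is.na(di), NA_integer_, time[di]), na.rm = TRUE)
      fill <- is.na(time) & !is.na(pmaxt)
      if (any(fill)) {
        time[fill] <- pmaxt[fill] + interval
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- ped
  out$time <- time
  not_imputed <- ped$id[is.na(time)]
  attr(out, "not_imputed") <- not_imputed
  if (length(not_imputed) > 0L) {
    warning(length(not_imputed),
            " record(s) still have missing time after imputation")
  }
  out
}

#' Diagnose parent/offspring time inconsistencies
#'
#' Lists records whose known parent was born in the same year or later
#' than the record itself. Imputation ([fix_birth_years()]) deliberately
#' does not enforce this; the check is separate.
#'
#' @param ped a `ped_table`.
#' @return Character vector of offending ids (empty when consistent).
#' @export
check_time_consistency <- function(ped) {
  ped <- as_ped_table(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  bad <- rep.int(FALSE, nrow(ped))
  for (pi in list(si, di)) {
    ok <- !is.na(pi) & !is.na(ped$time) & !is.na(ped$time[pi])
    bad[ok] <- bad[ok] | ped$time[pi][ok] >= ped$time[ok]
  }
  ped$id[bad]
}

#' Rebase a pedigree by dropping records
#'
#' Removes all records with `keep = FALSE`, including their role as
#' parents: surviving records whose parents were removed get those parent
#' links set to unknown, making them founders of the rebased pedigree.
#' Typical use is restricting an analysis to recent generations so that
#' the first kept generation becomes the base population.
#'
#' @param ped a `ped_table`.
#' @param keep logical vector, one value per record (`TRUE` = keep).
#' @return The rebased `ped_table`.
#' @export
set_base <- function(ped, keep) {
  ped <- as_ped_table(ped)
  if (!is.logical(keep) || length(keep) != nrow(ped) || anyNA(keep)) {
    stop("keep must be a complete logical vector with one value per record")
  }
  out <- ped[keep, , drop = FALSE]
  for (col in c("sire", "dam")) {
    gone <- !is.na(out[[col]]) & !(out[[col]] %in% out$id)
    out[[col]][gone] <- NA_character_
  }
  rownames(out) <- NULL
  keep_ped_attrs(out, ped)
}
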