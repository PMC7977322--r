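#' Expected gene-flow matrix of a pedigree
#'
#' Builds the lower-triangular gene-flow matrix `T = (I - P)^{-1}`,
#' where `P` holds the expected parental contributions (1/2 and 1/2 per
#' sire and dam, or 1/2 and 1/4 per sire and maternal grandsire), and
#' its path blocks `T_p`: `T` with all columns of individuals not on
#' path `p` zeroed. Breeding values satisfy `a = T w` with `w` the
#' Mendelian sampling terms, and the path partitions are `a_p = T_p w`.
#'
#' Rows and columns follow the canonical pedigree order of
#' [validate_and_sort()] and are labelled by individual id. The dense
#' matrices returned here are meant for inspection and testing of small
#' pedigrees.
#'
#' @param ped a [ped_table()].
#' @param path_column name of the path column (defaults to the
#'   `path_column` attribute).
#' @param max_n size guard for materialising the dense matrix.
#' @return A list with elements `T` (dense lower-triangular matrix) and
#'   `path_blocks` (named list of `T_p` matrices, one per path label).
#' @export
gene_flow_matrix <- function(ped, path_column = NULL, max_n = 5000L) {
  ped <- as_ped_table(ped)
  if (nrow(ped) > max_n) {
    stop("pedigree too large (", nrow(ped), " > ", max_n,
         ") to materialise a dense gene-flow matrix")
  }
  if (is.null(path_column)) path_column <- attr(ped, "path_column", exact = TRUE)
  if (is.null(path_column)) stop("path_column must be given")
  ped <- validate_and_sort(ped)
  L <- imp_matrix(ped)
  Tm <- as.matrix(Matrix::solve(L))
  dimnames(Tm) <- list(ped$id, ped$id)
  path <- as.character(ped[[path_column]])
  labels <- sort(unique(path), method = "radix")
  blocks <- lapply(labels, function(p) {
    B <- Tm
    B[, path != p] <- 0
    B
  })
  names(blocks) <- labels
  list(T = Tm, path_blocks = blocks)
}

## sparse I - P for a sorted pedigree (unit lower triangular)
imp_matrix <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id, nomatch = 0L)
  di <- match(ped$dam, ped$id, nomatch = 0L)
  coefs <- parent_coefficients(ped)
  ii <- c(seq_len(n), which(si > 0L), which(di > 0L))
  jj <- c(seq_len(n), si[si > 0L], di[di > 0L])
  xx <- c(rep.int(1, n),
          rep.int(-coefs[1L], sum(si > 0L)),
          rep.int(-coefs[2L], sum(di > 0L)))
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Matrix-route partitioning (testing oracle)
#'
#' Computes the same decomposition as [partition()] through sparse
#' linear algebra instead of pedigree recursion: the Mendelian sampling
#' terms are `w = (I - P) a` and each path partition solves the sparse
#' triangular system `(I - P) a_p = w_p`, where `w_p` keeps only the
#' terms of individuals on path `p` (equivalently `a_p = T_p w`). The
#' two routes are mathematically identical; this one exists as an
#' independent cross-check and is not meant for production use.
#'
#' @inheritParams partition
#' @param max_n size guard; beyond it use [partition()].
#' @return A `bv_partition`, identical in contract to [partition()].
#' @export
partition_matrix_oracle <- function(ped, path_column = NULL,
                                    trait_columns = NULL, strict = TRUE,
                                    max_n = 20000L) {
  prep <- prepare_partition(ped, path_column, trait_columns, strict)
  n <- nrow(prep$ped)
  if (n > max_n) {
    stop("pedigree too large (", n, " > ", max_n,
         ") for the matrix route; use partition() instead")
  }
  L <- imp_matrix(prep$ped)
  a <- prep$bv                      # n x T
  w <- as.matrix(L %*% a)           # Mendelian sampling terms
  pa <- a - w
  out <- list(info = prep$info)
  for (t in seq_along(prep$traits)) {
    tr <- prep$traits[t]
    df <- as.data.frame(prep$ped_in)
    df[[paste0(tr, "_pa")]] <- pa[prep$inv, t]
    df[[paste0(tr, "_w")]] <- w[prep$inv, t]
    pm <- matrix(0, n, length(prep$labels),
                 dimnames = list(NULL, paste0(tr, "_", prep$labels)))
    for (k in seq_along(prep$labels)) {
      wp <- w[, t]
      wp[prep$pathi != k] <- 0
      pm[, k] <- as.numeric(Matrix::solve(L, wp))
    }
    df <- cbind(df, as.data.frame(pm[prep$inv, , drop = FALSE]))
    out[[tr]] <- df
  }
  class(out) <- "bv_partition"
  out
}
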