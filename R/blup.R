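#' Sparse inverse numerator-relationship matrix
#'
#' Assembles `A^{-1}` directly from the pedigree with the standard
#' founder/non-founder rules, ignoring inbreeding: the Mendelian
#' sampling variance ratio is 1/2 with both parents known, 3/4 with
#' one, and 1 for founders. Requires sire-dam parental semantics and a
#' topologically sorted pedigree (sorted internally).
#'
#' @param ped a [ped_table()] in `"sire-dam"` mode.
#' @return Sparse symmetric matrix (class from the Matrix package),
#'   ordered and labelled like `validate_and_sort(ped)`.
#' @export
a_inverse <- function(ped) {
  ped <- validate_and_sort(as_ped_table(ped))
  if (parent_mode(ped) != "sire-dam") {
    stop("A-inverse assembly requires sire-dam parental semantics")
  }
  n <- nrow(ped)
  si <- match(ped$sire, ped$id, nomatch = 0L)
  di <- match(ped$dam, ped$id, nomatch = 0L)
  nk <- (si > 0L) + (di > 0L)
  alpha <- 1 / (1 - 0.25 * nk)  # 1, 4/3, 2 for 0, 1, 2 known parents
  i <- seq_len(n)
  ii <- i; jj <- i; xx <- alpha                        # (i, i) += alpha
  hs <- si > 0L
  ii <- c(ii, i[hs], si[hs], si[hs])
  jj <- c(jj, si[hs], i[hs], si[hs])
  xx <- c(xx, -alpha[hs] / 2, -alpha[hs] / 2, alpha[hs] / 4)
  hd <- di > 0L
  ii <- c(ii, i[hd], di[hd], di[hd])
  jj <- c(jj, di[hd], i[hd], di[hd])
  xx <- c(xx, -alpha[hd] / 2, -alpha[hd] / 2, alpha[hd] / 4)
  hb <- hs & hd
  ii <- c(ii, si[hb], di[hb])
  jj <- c(jj, di[hb], si[hb])
  xx <- c(xx, alpha[hb] / 4, alpha[hb] / 4)
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  dimnames(Ainv) <- list(ped$id, ped$id)
  Ainv
}

#' Pedigree BLUP: single-trait animal model
#'
#' Estimates breeding values from phenotypes and pedigree by solving
#' Henderson's mixed-model equations for the model
#' `y = mu + a + e`, with the overall mean as the only fixed effect and
#' animal effects `a ~ N(0, A sigma_a^2)` structured by the pedigree.
#' The variance ratio is `lambda = (1 - h2) / h2`. Individuals with a
#' missing phenotype contribute no data row but still receive an
#' estimate through the relationship structure (an unphenotyped
#' individual whose parents carry all the information gets exactly its
#' parent-average estimate).
#'
#' Inbreeding is ignored in `A^{-1}` (see [a_inverse()]).
#'
#' @param ped a [ped_table()] in `"sire-dam"` mode.
#' @param trait name of the phenotype column; `NA` marks unphenotyped
#'   individuals.
#' @param h2 heritability of the trait, in (0, 1).
#' @return Numeric vector of estimated breeding values aligned to the
#'   rows of `ped` (input order), with the estimated mean in the
#'   `"mean"` attribute.
#' @export
estimate_breeding_values <- function(ped, trait, h2) {
  ped0 <- as_ped_table(ped)
  if (!trait %in% names(ped0)) stop("phenotype column '", trait, "' not found")
  if (!is.numeric(h2) || length(h2) != 1L || h2 <= 0 || h2 >= 1) {
    stop("h2 must be a single value in (0, 1)")
  }
  ped <- validate_and_sort(ped0)
  y <- as.numeric(ped[[trait]])
  obs <- which(!is.na(y))
  if (length(obs) == 0L) stop("no phenotyped individuals for '", trait, "'")
  n <- nrow(ped)
  lambda <- (1 - h2) / h2
  Ainv <- a_inverse(ped)
  yo <- y[obs]
  ## W = [X Z] with X the all-ones mean column
  W <- Matrix::sparseMatrix(i = rep(seq_along(obs), 2L),
                            j = c(rep(1L, length(obs)), obs + 1L),
                            x = 1, dims = c(length(obs), n + 1L))
  C <- Matrix::forceSymmetric(Matrix::crossprod(W) +
    Matrix::bdiag(Matrix::Matrix(0, 1, 1), lambda * Ainv))
  rhs <- as.numeric(Matrix::crossprod(W, yo))
  ## MME coefficient matrix is symmetric positive definite: sparse Cholesky
  ch <- Matrix::Cholesky(C, LDL = FALSE, super = TRUE)
  sol <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  ahat_sorted <- sol[-1L]
  ahat <- ahat_sorted[match(ped0$id, ped$id)]
  attr(ahat, "mean") <- sol[1L]
  ahat
}
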