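#' Pedigree additive relationship matrix
#'
#' Builds the numerator relationship matrix A by the recursive tabular
#' method: `a_ii = 1 + F_i` where `F_i = 0.5 * a(sire_i, dam_i)` is the
#' inbreeding coefficient, and `a_ij = 0.5 * (a(j, sire_i) + a(j, dam_i))`
#' for any j preceding i. Unknown parents contribute zero relationship.
#' The pedigree is topologically sorted first; a cycle (an individual that
#' is its own ancestor) is an error.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam`; unknown parents
#'   as `NA`, `""` or `"0"`.
#' @param ids optional character vector: restrict the returned matrix to
#'   these individuals (ancestors are still used in the recursion).
#' @return symmetric numeric matrix with dimnames set to the ids; diagonal
#'   in `[1, 2]`.
#' @examples
#' ped <- data.frame(id = c("A", "B", "C"), sire = c(NA, NA, "A"),
#'                   dam = c(NA, NA, "B"))
#' build_A(ped)["A", "C"] # parent-offspring: 0.5
#' @export
build_A <- function(ped, ids = NULL) {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  id <- as.character(ped$id)
  if (anyDuplicated(id)) stop("duplicate ids in pedigree")
  clean <- function(x) {
    x <- as.character(x)
    x[x %in% c("", "0", "NA")] <- NA_character_
    x
  }
  sire <- clean(ped$sire)
  dam <- clean(ped$dam)
  unknown_parents <- stats::na.omit(setdiff(c(sire, dam), id))
  if (length(unknown_parents))
    stop("parents not present as individuals: ",
         paste(utils::head(unknown_parents, 5), collapse = ", "))

  ## Kahn topological sort; detects cycles
  n <- length(id)
  idx <- stats::setNames(seq_len(n), id)
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam), 0L, idx[dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) for (p in c(si[i], di[i])) if (p > 0L) {
    indeg[i] <- indeg[i] + 1L
    children[[p]] <- c(children[[p]], i)
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) stop("pedigree contains a cycle")

  A <- matrix(0, n, n, dimnames = list(id, id))
  pos <- integer(n)  # position of each individual in the processing order
  pos[order] <- seq_len(n)
  for (k in seq_len(n)) {
    i <- order[k]
    s <- si[i]; d <- di[i]
    if (k > 1L) {
      prev <- order[seq_len(k - 1L)]
      row_s <- if (s > 0L) A[s, prev] else 0
      row_d <- if (d > 0L) A[d, prev] else 0
      A[i, prev] <- A[prev, i] <- 0.5 * (row_s + row_d)
    }
    Fi <- if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
    A[i, i] <- 1 + Fi
  }
  if (!is.null(ids)) {
    missing_ids <- setdiff(ids, id)
    if (length(missing_ids))
      stop("ids not in pedigree: ", paste(utils::head(missing_ids, 5), collapse = ", "))
    A <- A[ids, ids, drop = FALSE]
  }
  A
}

# Monte-Carlo gene-dropping estimate of A: founders receive unique allele
# labels, alleles drop down the pedigree, and relationships are estimated
# as twice the proportion of identical-by-descent allele pairs. Used as an
# independent oracle for build_A in the test-suite.
gene_drop_A <- function(ped, n_drops = 1e5, seed = 1) {
  id <- as.character(ped$id)
  n <- length(id)
  idx <- stats::setNames(seq_len(n), id)
  clean <- function(x) {
    x <- as.character(x); x[x %in% c("", "0", "NA")] <- NA_character_; x
  }
  si <- ifelse(is.na(clean(ped$sire)), 0L, idx[clean(ped$sire)])
  di <- ifelse(is.na(clean(ped$dam)), 0L, idx[clean(ped$dam)])
  # process founders first, then anyone whose parents are already done
  processed <- logical(n)
  sequence_order <- integer(0)
  repeat {
    ready <- which(!processed)
    ready <- ready[(si[ready] == 0L | processed[pmax(si[ready], 1L)]) &
                   (di[ready] == 0L | processed[pmax(di[ready], 1L)])]
    if (!length(ready)) break
    sequence_order <- c(sequence_order, ready)
    processed[ready] <- TRUE
  }
  if (length(sequence_order) < n) stop("pedigree contains a cycle")

  with_seed(seed, {
    P <- matrix(0L, n, n_drops)  # paternal allele label
    M <- matrix(0L, n, n_drops)  # maternal allele label
    next_label <- 1L
    for (i in sequence_order) {
      if (si[i] == 0L) {
        P[i, ] <- next_label; next_label <- next_label + 1L
      } else {
        pick <- stats::runif(n_drops) < 0.5
        P[i, ] <- ifelse(pick, P[si[i], ], M[si[i], ])
      }
      if (di[i] == 0L) {
        M[i, ] <- next_label; next_label <- next_label + 1L
      } else {
        pick <- stats::runif(n_drops) < 0.5
        M[i, ] <- ifelse(pick, P[di[i], ], M[di[i], ])
      }
    }
    A <- matrix(0, n, n, dimnames = list(id, id))
    SE <- matrix(0, n, n, dimnames = list(id, id))
    for (i in seq_len(n)) for (j in i:n) {
      ibd <- (P[i, ] == P[j, ]) + (P[i, ] == M[j, ]) +
        (M[i, ] == P[j, ]) + (M[i, ] == M[j, ])
      if (i == j) {
        # a_ii = 1 + F_i, F_i = P(the two alleles of i are IBD)
        f <- (P[i, ] == M[i, ])
        A[i, i] <- 1 + mean(f)
        SE[i, i] <- stats::sd(f) / sqrt(n_drops)
      } else {
        k <- ibd / 4  # per-drop kinship estimate; a_ij = 2 * kinship
        A[i, j] <- A[j, i] <- 2 * mean(k)
        SE[i, j] <- SE[j, i] <- 2 * stats::sd(k) / sqrt(n_drops)
      }
    }
    list(A = A, SE = SE)
  })
}
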