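# Independent Wright path-counting oracle for kinship and inbreeding.
# Enumerates, for a pair (i, j), every common ancestor A and every pair
# of ancestor paths (i -> A, j -> A) sharing no individual except A;
# each such pair contributes (1/2)^(n1 + n2 + 1) * (1 + f_A), with n the
# number of parent links in a path and f_A the ancestor's own inbreeding
# (computed by the same rule on A's parents). Completely independent of
# the package's tabular recursion.

oracle_paths_up <- function(id, mo, fa) {
  out <- list(id)
  for (p in c(mo[[id]], fa[[id]])) {
    if (!is.na(p)) {
      for (pp in oracle_paths_up(p, mo, fa)) {
        out <- c(out, list(c(id, pp)))
      }
    }
  }
  out
}

oracle_maker <- function(ped) {
  mo <- as.list(setNames(ped$mother_id, ped$id))
  fa <- as.list(setNames(ped$father_id, ped$id))
  memo <- new.env(parent = emptyenv())
  kin <- function(i, j) {
    key <- paste(sort(c(i, j)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      f <- if (!is.na(mo[[i]]) && !is.na(fa[[i]])) kin(fa[[i]], mo[[i]]) else 0
      0.5 * (1 + f)
    } else {
      pi_ <- oracle_paths_up(i, mo, fa)
      pj_ <- oracle_paths_up(j, mo, fa)
      tot <- 0
      for (p1 in pi_) {
        for (p2 in pj_) {
          a <- p1[length(p1)]
          if (a != p2[length(p2)]) next
          if (length(intersect(p1, p2)) != 1L) next
          fa_a <- if (!is.na(mo[[a]]) && !is.na(fa[[a]])) {
            kin(fa[[a]], mo[[a]])
          } else {
            0
          }
          tot <- tot + 0.5^(length(p1) + length(p2) - 1) * (1 + fa_a)
        }
      }
      tot
    }
    memo[[key]] <- val
    val
  }
  kin
}

oracle_kinship_matrix <- function(ped) {
  kin <- oracle_maker(ped)
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (a in seq_len(n)) {
    for (b in seq_len(a)) {
      K[a, b] <- K[b, a] <- kin(ped$id[a], ped$id[b])
    }
  }
  K
}
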