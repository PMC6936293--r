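#' Truth tables over k Boolean variables
#'
#' A truth table holds one output value per assignment of `x0 ..
#' x(k-1)`: `1`, `0` or `NA` for don't-care. Assignments are indexed by
#' their decimal encoding with `x0` as the most significant bit, matching
#' the machine-state encoding, so `values[v + 1]` is the output for
#' assignment decimal `v`.
#'
#' @param values Integer/NA vector of length `2^k`.
#' @param k Number of variables.
#' @return An object of class `truth_table`.
#' @export
truth_table <- function(values, k) {
  if (length(values) != 2^k)
    stop("`values` must have length 2^k", call. = FALSE)
  values <- as.integer(values)
  if (!all(values %in% c(0L, 1L, NA_integer_)))
    stop("table values must be 0, 1 or NA", call. = FALSE)
  structure(list(values = values, k = as.integer(k)), class = "truth_table")
}

#' Reconstruct one electrode's truth table from a response map
#'
#' The response map `g` (see [g_of_t()]) sends input decimals to machine
#' states; bit `e` of the image state is the output of electrode `e`'s
#' Boolean function for that input. Inputs absent from `g` become
#' don't-cares (they were never observed, so forcing them to 0 would
#' fabricate data); set `strict = TRUE` to force them to 0 instead.
#' Input 0 is always fixed to output 0: an unstimulated network stays
#' quiescent.
#'
#' @param g Named integer vector from [g_of_t()].
#' @param electrode Electrode index `e`, `0 <= e < k`.
#' @param k Number of electrodes / variables.
#' @param strict Treat unobserved inputs as 0 instead of don't-care.
#' @return A [truth_table].
#' @export
table_from_g <- function(g, electrode, k, strict = FALSE) {
  if (electrode < 0L || electrode >= k)
    stop("`electrode` must be in 0 .. k-1", call. = FALSE)
  values <- rep(NA_integer_, 2^k)
  values[1] <- 0L
  for (nm in names(g)) {
    v <- as.integer(nm)
    values[v + 1L] <- pattern_bits(g[[nm]], k)[electrode + 1L]
  }
  if (strict) values[is.na(values)] <- 0L
  truth_table(values, k)
}

# cube representation: assignment bits with x0 at bit position k-1;
# a cube is (val, mask) with mask bits marking free variables and the
# masked bits of val zeroed.  A cube covers assignment a iff
# bitwAnd(a, ~mask) == val.
popcount <- function(x) vapply(x, function(v) sum(intToBits(v) != 0), 0L)

cube_covers <- function(val, mask, a, k) {
  full <- 2^k - 1
  bitwAnd(a, bitwAnd(full, bitwNot(mask))) == val
}

cube_literals <- function(mask, k) k - popcount(mask)

#' Minimize a truth table to a disjunctive normal form
#'
#' Quine–McCluskey prime-implicant generation followed by exact minimum
#' cover selection (essential primes first, then branch-and-bound over
#' the rest). Don't-care rows may be absorbed into implicants but are
#' never required to be covered. Among the minimum-size covers, ties are
#' broken by fewest total literals and then lexicographically on the
#' rendered terms, so the result is deterministic. The returned DNF
#' always evaluates identically to the table on every specified row.
#'
#' @param table A [truth_table].
#' @return An object of class `dnf` with fields `terms` (matrix, one row
#'   per product term, entries 1 = positive literal, 0 = negated, NA =
#'   absent), `cubes` (internal `(val, mask)` pairs) and `k`. An empty
#'   term set denotes the constant FALSE.
#' @export
minimize_dnf <- function(table) {
  stopifnot(inherits(table, "truth_table"))
  k <- table$k
  minterms <- which(table$values == 1L) - 1L
  dontcares <- which(is.na(table$values)) - 1L
  if (length(minterms) == 0L) return(new_dnf(matrix(0, 0, 2), k))

  primes <- qm_primes(c(minterms, dontcares), k)
  cover <- qm_min_cover(primes, minterms, k)
  new_dnf(primes[cover, , drop = FALSE], k)
}

qm_primes <- function(terms, k) {
  cubes <- unique(cbind(val = as.integer(terms), mask = 0L))
  primes <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("val", "mask")))
  while (nrow(cubes) > 0L) {
    combined <- rep(FALSE, nrow(cubes))
    nxt <- list()
    for (m in unique(cubes[, "mask"])) {
      grp <- which(cubes[, "mask"] == m)
      if (length(grp) < 2L) next
      vals <- cubes[grp, "val"]
      for (a in seq_along(grp)) for (b in seq_along(grp)) {
        if (a >= b) next
        diff <- bitwXor(vals[a], vals[b])
        if (popcount(diff) == 1L) {
          combined[grp[c(a, b)]] <- TRUE
          nxt[[length(nxt) + 1L]] <- c(bitwAnd(vals[a], bitwNot(diff)),
                                       bitwOr(m, diff))
        }
      }
    }
    primes <- rbind(primes, cubes[!combined, , drop = FALSE])
    cubes <- if (length(nxt)) unique(do.call(rbind, nxt)) else
      matrix(integer(0), 0, 2)
    if (nrow(cubes)) colnames(cubes) <- c("val", "mask")
  }
  unique(primes)
}

qm_min_cover <- function(primes, minterms, k) {
  np <- nrow(primes)
  covers <- matrix(FALSE, np, length(minterms))
  for (p in seq_len(np))
    covers[p, ] <- cube_covers(primes[p, "val"], primes[p, "mask"],
                               minterms, k)

  chosen <- integer(0)
  remaining <- seq_along(minterms)
  # essential primes
  repeat {
    ess <- integer(0)
    for (m in remaining) {
      who <- which(covers[, m])
      if (length(who) == 1L && !(who %in% chosen)) ess <- c(ess, who)
    }
    ess <- setdiff(unique(ess), chosen)
    if (length(ess) == 0L) break
    chosen <- c(chosen, ess)
    remaining <- remaining[!apply(covers[chosen, remaining, drop = FALSE],
                                  2, any)]
    if (length(remaining) == 0L) break
  }

  if (length(remaining) > 0L) {
    cand <- which(apply(covers[, remaining, drop = FALSE], 1, any))
    cand <- setdiff(cand, chosen)
    best <- qm_search_cover(covers, cand, remaining, k, primes)
    chosen <- c(chosen, best)
  }
  sort(chosen)
}

# branch-and-bound search for the smallest completion of the cover, with
# (total literal count, lexicographic term order) tie-breaks; exact: only
# strictly-larger partial covers are pruned, so every minimum-size cover
# is reachable and compared on the tie-break keys
qm_search_cover <- function(covers, cand, remaining, k, primes) {
  lits <- cube_literals(primes[, "mask"], k)
  keyfun <- function(set)
    paste(sort(apply(primes[set, , drop = FALSE], 1, paste, collapse = "/")),
          collapse = ";")
  best <- NULL   # list(set, size, lits, key)
  consider <- function(set) {
    score <- list(set = set, size = length(set), lits = sum(lits[set]),
                  key = keyfun(set))
    if (is.null(best) || score$size < best$size ||
        (score$size == best$size &&
         (score$lits < best$lits ||
          (score$lits == best$lits && score$key < best$key))))
      best <<- score
  }
  recurse <- function(chosen, rem) {
    if (length(rem) == 0L) { consider(chosen); return(invisible()) }
    if (!is.null(best) && length(chosen) + 1L > best$size) return(invisible())
    # branch on the uncovered minterm with fewest covering candidates
    ncov <- vapply(rem, function(m) sum(covers[cand, m]), 0L)
    m <- rem[which.min(ncov)]
    for (p in cand[covers[cand, m]]) {
      rem2 <- rem[!covers[p, rem]]
      recurse(c(chosen, p), rem2)
    }
    invisible()
  }
  recurse(integer(0), remaining)
  if (is.null(best)) integer(0) else best$set
}

new_dnf <- function(cubes, k) {
  cubes <- matrix(as.integer(cubes), ncol = 2,
                  dimnames = list(NULL, c("val", "mask")))
  nterm <- nrow(cubes)
  terms <- matrix(NA_integer_, nterm, k,
                  dimnames = list(NULL, paste0("x", seq_len(k) - 1L)))
  for (tix in seq_len(nterm)) {
    for (v in seq_len(k) - 1L) {
      bitpos <- k - 1L - v          # x0 is the most significant bit
      bit <- bitwAnd(bitwShiftR(cubes[tix, "mask"], bitpos), 1L)
      if (bit == 0L)
        terms[tix, v + 1L] <-
          bitwAnd(bitwShiftR(cubes[tix, "val"], bitpos), 1L)
    }
  }
  ord <- order(rowSums(!is.na(terms)),
               apply(terms, 1, function(r) paste(ifelse(is.na(r), "-", r),
                                                 collapse = "")))
  structure(list(terms = terms[ord, , drop = FALSE],
                 cubes = cubes[ord, , drop = FALSE], k = as.integer(k)),
            class = "dnf")
}

#' Evaluate a DNF on assignments
#'
#' @param dnf A `dnf`.
#' @param assignments Integer vector of assignment decimals (`x0` = most
#'   significant bit).
#' @return Logical vector.
#' @export
eval_dnf <- function(dnf, assignments) {
  if (nrow(dnf$cubes) == 0L) return(rep(FALSE, length(assignments)))
  out <- rep(FALSE, length(assignments))
  for (tix in seq_len(nrow(dnf$cubes)))
    out <- out | cube_covers(dnf$cubes[tix, "val"], dnf$cubes[tix, "mask"],
                             assignments, dnf$k)
  out
}

#' Check a DNF against a truth table
#'
#' @param dnf A `dnf`.
#' @param table A [truth_table].
#' @return `TRUE` iff the DNF matches the table on every specified
#'   (non-`NA`) row.
#' @export
dnf_matches_table <- function(dnf, table) {
  a <- seq_len(2^table$k) - 1L
  spec <- !is.na(table$values)
  all(eval_dnf(dnf, a[spec]) == (table$values[spec] == 1L))
}

#' Render a DNF as text
#'
#' Terms are ordered by (literal count, lexicographic), literals by
#' variable index; negation is written with a combining overbar
#' (`x̄1`). The constant FALSE renders as `"0"`.
#'
#' @param dnf A `dnf`.
#' @return Character scalar.
#' @export
dnf_to_string <- function(dnf) {
  if (nrow(dnf$terms) == 0L) return("0")
  term_str <- apply(dnf$terms, 1, function(r) {
    ix <- which(!is.na(r))
    paste(ifelse(r[ix] == 1L, paste0("x", ix - 1L),
                 paste0("x̄", ix - 1L)), collapse = "·")
  })
  paste(term_str, collapse = " + ")
}

#' @export
print.dnf <- function(x, ...) {
  cat(sprintf("<dnf> %d term(s) over %d variable(s)\n", nrow(x$terms), x$k))
  cat("  ", dnf_to_string(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("<truth_table> k = %d: %d ones, %d zeros, %d don't-cares\n",
              x$k, sum(x$values == 1L, na.rm = TRUE),
              sum(x$values == 0L, na.rm = TRUE), sum(is.na(x$values))))
  invisible(x)
}
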