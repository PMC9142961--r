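# Closed-form Bateman solution for serial decay chains.
#
# Atom numbers are carried internally in units of kBq.min (activity / lambda),
# activities in kBq. The distinct-lambda closed form is the primary path; when
# any two decay constants agree within 1e-9 relative, the solution switches to
# the matrix exponential of the bidiagonal rate matrix, which evaluates the
# confluent limit exactly without dividing by a vanishing difference.

.lambda_degenerate <- function(lam, rel = 1e-9) {
  fin <- lam[is.finite(lam) & lam > 0]
  if (length(fin) < 2L) return(FALSE)
  d <- abs(outer(fin, fin, "-")) / outer(fin, fin, pmax)
  any(d[upper.tri(d)] <= rel)
}

# atom numbers at elapsed (vector, minutes) given initial atoms n0 (length n)
bateman_atoms <- function(chain, n0, elapsed) {
  lam <- chain$lambda
  b <- chain$branching
  n <- chain$n
  nt <- length(elapsed)
  if (.lambda_degenerate(lam))
    return(bateman_atoms_expm(chain, n0, elapsed))
  out <- matrix(0, nt, n, dimnames = list(NULL, chain$names))
  for (s in seq_len(n)) {
    if (n0[s] == 0) next
    for (m in s:n) {
      idx <- s:m
      coef <- if (m > s) prod(b[s:(m - 1L)] * lam[s:(m - 1L)]) else 1
      if (coef == 0) next
      terms <- matrix(0, nt, length(idx))
      for (k in seq_along(idx)) {
        i <- idx[k]
        denom <- prod(lam[setdiff(idx, i)] - lam[i])
        terms[, k] <- exp(-lam[i] * elapsed) / denom
      }
      out[, m] <- out[, m] + n0[s] * coef * rowSums(terms)
    }
  }
  out
}

bateman_atoms_expm <- function(chain, n0, elapsed) {
  n <- chain$n
  M <- matrix(0, n, n)
  diag(M) <- -chain$lambda
  if (n > 1L)
    M[cbind(2:n, 1:(n - 1L))] <- chain$branching * chain$lambda[1:(n - 1L)]
  out <- t(vapply(elapsed, function(tt)
    as.numeric(Matrix::expm(M * tt) %*% n0), numeric(n)))
  dimnames(out) <- list(NULL, chain$names)
  out
}

#' Chain activities after an elapsed time (Bateman solution)
#'
#' Propagates every chain member's activity forward by `elapsed` using the
#' closed-form Bateman solution of the serial decay chain (distinct decay
#' constants), or an exact matrix-exponential limit evaluation when two decay
#' constants coincide within 1e-9 relative. Members absent from `initial` start
#' at zero. A stable terminus always reports activity 0.
#'
#' @param chain a [decay_chain()].
#' @param initial an [activity_state()] or named activity vector (kBq).
#' @param elapsed non-negative elapsed time(s); scalar or vector.
#' @param unit time unit of `elapsed` (default minutes).
#' @return for scalar `elapsed`, an [activity_state()] at the advanced time;
#'   for a vector, a numeric matrix (rows = times, columns = members, kBq).
#' @examples
#' ch <- ac225_chain()
#' bateman_activities(ch, c("Ac-225" = 50), 9.9, unit = "day")
#' @export
bateman_activities <- function(chain, initial, elapsed, unit = "min") {
  if (inherits(initial, "activity_state")) {
    t0 <- initial$time
    a0 <- initial$activities
  } else {
    t0 <- 0
    a0 <- initial
  }
  if (is.null(names(a0))) stop("`initial` must be named", call. = FALSE)
  unknown <- setdiff(names(a0), chain$names)
  if (length(unknown))
    stop("initial activities name nuclides not in the chain: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (any(!is.finite(elapsed)) || any(elapsed < 0))
    stop("`elapsed` must be non-negative", call. = FALSE)
  el <- to_minutes(elapsed, unit)
  act0 <- stats::setNames(numeric(chain$n), chain$names)
  act0[names(a0)] <- a0
  if (any(act0 < 0)) stop("activities must be >= 0", call. = FALSE)
  lam <- chain$lambda
  if (any(act0[lam == 0] > 0))
    stop("a stable member cannot carry activity", call. = FALSE)
  n0 <- ifelse(lam > 0, act0 / lam, 0)
  atoms <- bateman_atoms(chain, n0, el)
  act <- sweep(atoms, 2L, lam, `*`)
  act[act < 0 & act > -1e-12 * max(act0)] <- 0 # clip closed-form round-off
  if (length(el) == 1L)
    activity_state(act[1L, ], time = t0 + el)
  else
    act
}

#' Ingrown daughter activity supported by a parent
#'
#' Activity of `daughter` at `elapsed` when only `parent` (at
#' `parent_activity` kBq) was present at time zero. Non-decreasing in time and
#' approaching `parent_activity * equilibrium_ratio()` (times the parent's own
#' decay) as transient equilibrium is established.
#'
#' @inheritParams equilibrium_ratio
#' @param parent_activity parent activity at time zero, kBq.
#' @param elapsed elapsed time(s), non-negative.
#' @param unit time unit of `elapsed`.
#' @return daughter activity in kBq (vectorised over `elapsed`).
#' @export
supported_daughter_activity <- function(chain, parent, daughter,
                                        parent_activity, elapsed,
                                        unit = "min") {
  ip <- match(parent, chain$names)
  id <- match(daughter, chain$names)
  if (is.na(ip) || is.na(id)) stop("nuclide not in chain", call. = FALSE)
  if (id <= ip)
    stop("`daughter` must be downstream of `parent`", call. = FALSE)
  if (parent_activity < 0) stop("`parent_activity` must be >= 0", call. = FALSE)
  init <- stats::setNames(parent_activity, parent)
  act <- bateman_activities(chain, init, elapsed, unit = unit)
  if (inherits(act, "activity_state")) act$activities[[daughter]]
  else unname(act[, daughter])
}

# the lambda(parent) eigenmode: activities of all members in transient
# equilibrium with 1 kBq of parent (used to seed equilibrated samples)
equilibrium_state <- function(chain, parent = chain$names[1L]) {
  ip <- match(parent, chain$names)
  act <- stats::setNames(numeric(chain$n), chain$names)
  act[ip] <- 1
  if (ip < chain$n) for (j in (ip + 1L):chain$n) {
    if (chain$lambda[j] == 0) break
    act[j] <- equilibrium_ratio(chain, parent, chain$names[j])
  }
  act
}
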