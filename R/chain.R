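# minutes per unit; internal time unit is the minute, internal activity unit kBq
.time_factors <- c(ms = 1 / 60000, s = 1 / 60, min = 1, h = 60, day = 1440)

#' Convert a duration to minutes
#'
#' @param x numeric duration(s).
#' @param unit one of `"ms"`, `"s"`, `"min"`, `"h"`, `"day"`.
#' @return duration in minutes.
#' @export
to_minutes <- function(x, unit = "min") {
  unit <- match.arg(unit, names(.time_factors))
  x * .time_factors[[unit]]
}

#' Define a nuclide by its half-life
#'
#' The decay constant is derived as \eqn{\lambda = \ln 2 / t_{1/2}} so the
#' identity \eqn{\lambda \, t_{1/2} = \ln 2} holds to machine precision.
#' A stable terminus is represented by an infinite half-life (zero decay
#' constant).
#'
#' @param name character label, e.g. `"Ac-225"`.
#' @param half_life positive half-life (may be `Inf` for a stable nuclide).
#' @param unit time unit of `half_life`: `"ms"`, `"s"`, `"min"`, `"h"` or `"day"`.
#' @return an object of class `"nuclide"` with fields `name`, `half_life`
#'   (minutes) and `decay_constant` (1/min).
#' @examples
#' nuclide("Bi-213", 45.6, "min")
#' @export
nuclide <- function(name, half_life, unit = "min") {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name))
    stop("`name` must be a single non-empty string", call. = FALSE)
  if (!is.numeric(half_life) || length(half_life) != 1L || is.na(half_life) ||
      half_life <= 0)
    stop("`half_life` must be a single positive number", call. = FALSE)
  hl <- to_minutes(half_life, unit)
  structure(
    list(name = name, half_life = hl,
         decay_constant = if (is.finite(hl)) log(2) / hl else 0),
    class = "nuclide"
  )
}

#' @export
print.nuclide <- function(x, ...) {
  hl <- if (is.finite(x$half_life)) sprintf("%g min", x$half_life) else "stable"
  cat(sprintf("<nuclide> %s  t1/2 = %s  lambda = %g /min\n",
              x$name, hl, x$decay_constant))
  invisible(x)
}

#' Assemble a serial decay chain
#'
#' Members are strictly ordered parent-to-daughter. Only the last member may be
#' stable. Branching fractions apply to each parent-to-daughter link and must
#' lie in (0, 1].
#'
#' @param nuclides list of [nuclide()] objects, ordered parent first.
#' @param branching numeric vector of per-link branching fractions, length
#'   `length(nuclides) - 1`; defaults to all 1.
#' @return object of class `"decay_chain"` with fields `names`, `half_life`,
#'   `lambda`, `branching`, `n`.
#' @examples
#' decay_chain(list(nuclide("Ac-225", 9.9, "day"), nuclide("Fr-221", 5, "min")))
#' @export
decay_chain <- function(nuclides, branching = NULL) {
  if (!is.list(nuclides) || length(nuclides) < 1L ||
      !all(vapply(nuclides, inherits, logical(1), "nuclide")))
    stop("`nuclides` must be a non-empty list of nuclide objects", call. = FALSE)
  nm <- vapply(nuclides, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("chain members must have unique names (no cycles)", call. = FALSE)
  hl <- vapply(nuclides, `[[`, numeric(1), "half_life")
  lam <- vapply(nuclides, `[[`, numeric(1), "decay_constant")
  if (any(!is.finite(hl[-length(hl)])))
    stop("only the terminal chain member may be stable", call. = FALSE)
  n <- length(nuclides)
  if (is.null(branching)) branching <- rep(1, max(n - 1L, 0L))
  if (length(branching) != n - 1L)
    stop("`branching` must have one fraction per link", call. = FALSE)
  if (n > 1L && (any(branching <= 0) || any(branching > 1)))
    stop("branching fractions must lie in (0, 1]", call. = FALSE)
  structure(
    list(names = nm, half_life = hl, lambda = lam,
         branching = as.numeric(branching), n = n, nuclides = nuclides),
    class = "decay_chain"
  )
}

#' @export
print.decay_chain <- function(x, ...) {
  cat("<decay_chain> ", paste(x$names, collapse = " -> "), "\n", sep = "")
  for (i in seq_len(x$n)) {
    hl <- if (is.finite(x$half_life[i])) sprintf("%-12g min", x$half_life[i])
          else "stable"
    br <- if (i < x$n) sprintf("  branch %.3g", x$branching[i]) else ""
    cat(sprintf("  %-8s t1/2 %s%s\n", x$names[i], hl, br))
  }
  invisible(x)
}

#' Read a decay chain from a YAML definition
#'
#' The file lists `nuclides:` (each with `name`, `half_life`, `unit`) and an
#' optional `branching:` vector; see the packaged `ac225_chain.yaml` for the
#' format.
#'
#' @param path path to the YAML file.
#' @param drop character vector of member names to collapse out of the chain
#'   (the link through a dropped member keeps the product of its branching
#'   fractions). Used to treat very short-lived members as being in
#'   instantaneous equilibrium with their parent.
#' @return a [decay_chain()].
#' @export
read_chain <- function(path, drop = character()) {
  spec <- yaml::read_yaml(path)
  nucs <- lapply(spec$nuclides, function(s)
    nuclide(s$name, if (is.null(s$half_life)) Inf else s$half_life,
            if (is.null(s$unit)) "min" else s$unit))
  br <- if (is.null(spec$branching)) NULL else as.numeric(spec$branching)
  ch <- decay_chain(nucs, br)
  if (length(drop)) ch <- collapse_members(ch, drop)
  ch
}

# remove members (e.g. At-217) treating them as instantaneous: the incoming and
# outgoing branching fractions multiply across the removed link
collapse_members <- function(chain, drop) {
  keep <- !(chain$names %in% drop)
  if (!keep[1L])
    stop("cannot collapse the chain parent", call. = FALSE)
  br <- chain$branching
  # fold branching of removed member i into the preceding surviving link
  new_br <- numeric(0)
  acc <- 1
  for (i in seq_len(chain$n - 1L)) {
    acc <- acc * br[i]
    if (keep[i + 1L]) { new_br <- c(new_br, acc); acc <- 1 }
  }
  decay_chain(chain$nuclides[keep], new_br)
}

#' The default Ac-225 decay chain
#'
#' Loads the packaged chain definition (Ac-225 9.9 d, Fr-221 5 min, At-217
#' 32.3 ms, Bi-213 45.6 min, stable Bi-209). By default At-217 is collapsed
#' into its parent link: its half-life is below 1e-5 of any counting interval,
#' so it is treated as in instantaneous equilibrium with Fr-221, which keeps
#' the Bateman solution well conditioned. Set `collapse_at217 = FALSE` for the
#' full four-member solution (used e.g. to cross-check against an ODE
#' integrator).
#'
#' @param collapse_at217 logical; drop At-217 as instantaneous (default TRUE).
#' @param file optional path to an alternative YAML chain definition.
#' @return a [decay_chain()].
#' @export
ac225_chain <- function(collapse_at217 = TRUE, file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "ac225_chain.yaml", package = "alphachain",
                        mustWork = TRUE)
  read_chain(file, drop = if (collapse_at217) "At-217" else character())
}

#' Per-nuclide activities at a reference time
#'
#' A light container pairing a named activity vector (kBq) with the time (in
#' minutes on the study clock) at which it applies.
#'
#' @param activities named non-negative numeric vector of activities in kBq.
#' @param time reference time in minutes (default 0).
#' @return object of class `"activity_state"`.
#' @export
activity_state <- function(activities, time = 0) {
  if (is.null(names(activities)) || any(!nzchar(names(activities))))
    stop("`activities` must be a named vector", call. = FALSE)
  if (any(!is.finite(activities)) || any(activities < 0))
    stop("activities must be finite and >= 0", call. = FALSE)
  structure(list(activities = unlist(activities), time = time),
            class = "activity_state")
}

#' @export
print.activity_state <- function(x, ...) {
  cat(sprintf("<activity_state> at t = %g min\n", x$time))
  print(round(x$activities, 6))
  invisible(x)
}

#' Asymptotic daughter-to-parent activity ratio
#'
#' For a parent feeding a (segment of a) serial chain, the late-time activity
#' ratio \eqn{A_d / A_p} once transient equilibrium is established. For a
#' single link this is \eqn{\lambda_d / (\lambda_d - \lambda_p)}; in the
#' secular limit (\eqn{\lambda_d \gg \lambda_p}) the ratio tends to 1. The
#' formula is general: no assumption that the daughter is much shorter lived,
#' but every decay constant downstream through the daughter must exceed the
#' parent's, otherwise no transient equilibrium exists and an error is raised.
#'
#' @param chain a [decay_chain()] containing both nuclides.
#' @param parent,daughter member names, parent upstream of daughter.
#' @return dimensionless activity ratio.
#' @examples
#' equilibrium_ratio(ac225_chain(), "Ac-225", "Fr-221")
#' @export
equilibrium_ratio <- function(chain, parent, daughter) {
  ip <- match(parent, chain$names)
  id <- match(daughter, chain$names)
  if (is.na(ip) || is.na(id)) stop("nuclide not in chain", call. = FALSE)
  if (id <= ip) stop("`daughter` must be downstream of `parent`", call. = FALSE)
  lam <- chain$lambda
  lp <- lam[ip]
  seg <- (ip + 1L):id
  if (any(lam[seg] <= lp * (1 + 1e-9)))
    stop("no transient equilibrium: a downstream decay constant does not exceed the parent's",
         call. = FALSE)
  (lam[id] / lp) * prod(chain$branching[ip:(id - 1L)] * lam[ip:(id - 1L)]) /
    prod(lam[seg] - lp)
}
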