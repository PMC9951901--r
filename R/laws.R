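# Distribution descriptors for the synthetic-data generators.  A "law" is a
# small tagged list; sample_law() draws from it with optional truncation to a
# legal range (rejection sampling for the gaussian family).

#' Distribution laws for synthetic placement
#'
#' Constructors for the one-dimensional distribution descriptors used by the
#' droplet generator to place antioxidant molecules: radial laws are in
#' angstroms, angle laws in degrees.
#'
#' @param mean,sd mean and standard deviation (gaussian family).
#' @param min,max bounds (uniform family).
#' @param at point mass location (delta family).
#' @param components list of laws (mixture family).
#' @param weights mixture weights, recycled to the number of components and
#'   normalized to sum to one.
#' @return an object of class `dist_law`.
#' @examples
#' law_gaussian(31, 3)
#' law_mixture(list(law_delta(55.5), law_delta(82.5)))
#' @export
law_gaussian <- function(mean, sd) {
  stopifnot(is.finite(mean), is.finite(sd), sd >= 0)
  structure(list(family = "gaussian", mean = mean, sd = sd),
            class = "dist_law")
}

#' @rdname law_gaussian
#' @export
law_uniform <- function(min, max) {
  stopifnot(is.finite(min), is.finite(max), max > min)
  structure(list(family = "uniform", min = min, max = max),
            class = "dist_law")
}

#' @rdname law_gaussian
#' @export
law_delta <- function(at) {
  stopifnot(is.finite(at))
  structure(list(family = "delta", at = at), class = "dist_law")
}

#' @rdname law_gaussian
#' @export
law_mixture <- function(components, weights = 1) {
  stopifnot(length(components) >= 1L,
            all(vapply(components, inherits, logical(1L), "dist_law")))
  w <- rep_len(weights, length(components))
  stopifnot(all(w > 0))
  structure(list(family = "mixture", components = components,
                 weights = w / sum(w)),
            class = "dist_law")
}

#' @export
print.dist_law <- function(x, ...) {
  if (x$family == "mixture") {
    cat("<dist_law> mixture of", length(x$components), "components\n")
  } else {
    cat("<dist_law>", x$family, ":",
        paste(names(x)[-1L], unlist(x[-1L]), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Draw from a distribution law
#'
#' @param law a [law_gaussian()]-style descriptor.
#' @param n number of draws.
#' @param lower,upper legal range; gaussian draws are rejection-truncated to
#'   it, uniform/delta parameters must already lie inside it.
#' @return numeric vector of length `n`.
#' @export
sample_law <- function(law, n, lower = -Inf, upper = Inf) {
  stopifnot(inherits(law, "dist_law"), n >= 0)
  if (n == 0L) return(numeric(0L))
  switch(law$family,
    delta = {
      if (law$at < lower || law$at > upper)
        stop("delta law location outside the legal range [", lower, ", ",
             upper, "]", call. = FALSE)
      rep(law$at, n)
    },
    uniform = {
      if (law$min < lower || law$max > upper)
        stop("uniform law bounds outside the legal range", call. = FALSE)
      stats::runif(n, law$min, law$max)
    },
    gaussian = {
      if (law$sd == 0) return(sample_law(law_delta(law$mean), n, lower, upper))
      out <- numeric(0L)
      for (i in 1:100) {
        draw <- stats::rnorm(2L * n, law$mean, law$sd)
        out <- c(out, draw[draw >= lower & draw <= upper])
        if (length(out) >= n) break
      }
      if (length(out) < n)
        stop("gaussian law has negligible mass inside [", lower, ", ",
             upper, "]", call. = FALSE)
      out[seq_len(n)]
    },
    mixture = {
      idx <- sample.int(length(law$components), n, replace = TRUE,
                        prob = law$weights)
      out <- numeric(n)
      for (k in unique(idx)) {
        sel <- idx == k
        out[sel] <- sample_law(law$components[[k]], sum(sel), lower, upper)
      }
      out
    },
    stop("unknown law family: ", law$family, call. = FALSE))
}

#' Orientation laws for antioxidant placement
#'
#' The tilt of a rigid antioxidant at the droplet interface is described by
#' three angles against the radial vector: alpha (para axis), beta (center of
#' mass to C6) and gamma (aromatic plane).  A rigid placement has only three
#' rotational degrees of freedom and the spin about the radial vector leaves
#' all three angles unchanged, so at most two of them can be prescribed
#' independently; the remaining angle follows from the molecular geometry.
#' Four sampling modes are therefore offered:
#'
#' * `orient_alpha_beta(alpha, beta)` — draw alpha and beta independently
#'   from two laws (rejecting geometrically infeasible pairs), realize them
#'   constructively, then apply a uniform spin about the radial vector.
#' * `orient_joint(centers, sd, weights)` — draw the (alpha, beta) pair from
#'   a mixture of isotropic components centered at the rows of `centers`
#'   (degrees); `sd = 0` gives point components.
#' * `orient_gamma(gamma)` — draw gamma from a law on \[0, 90\], align the
#'   ring-plane normal accordingly (random hemisphere and azimuth), spin
#'   freely about the normal; alpha and beta then follow.
#' * `orient_random()` — uniform random rigid rotation.
#'
#' @param alpha,beta,gamma `dist_law` descriptors in degrees.
#' @param centers numeric matrix with one (alpha, beta) row per component.
#' @param sd per-component isotropic spread in degrees (recycled).
#' @param weights mixture weights.
#' @return an object of class `orientation_law`.
#' @examples
#' orient_joint(rbind(c(55.5, 64.5), c(82.5, 154.5)), sd = 6)
#' orient_gamma(law_delta(90))
#' @export
orient_alpha_beta <- function(alpha, beta) {
  stopifnot(inherits(alpha, "dist_law"), inherits(beta, "dist_law"))
  structure(list(mode = "ab", alpha = alpha, beta = beta),
            class = "orientation_law")
}

#' @rdname orient_alpha_beta
#' @export
orient_joint <- function(centers, sd = 0, weights = 1) {
  centers <- rbind(centers)
  stopifnot(ncol(centers) == 2L, all(is.finite(centers)),
            all(centers[, 1L] >= 0 & centers[, 1L] <= 180),
            all(centers[, 2L] >= 0 & centers[, 2L] <= 180))
  sd <- rep_len(sd, nrow(centers))
  w <- rep_len(weights, nrow(centers))
  stopifnot(all(sd >= 0), all(w > 0))
  structure(list(mode = "joint", centers = centers, sd = sd,
                 weights = w / sum(w)),
            class = "orientation_law")
}

#' @rdname orient_alpha_beta
#' @export
orient_gamma <- function(gamma) {
  stopifnot(inherits(gamma, "dist_law"))
  structure(list(mode = "gamma", gamma = gamma), class = "orientation_law")
}

#' @rdname orient_alpha_beta
#' @export
orient_random <- function() {
  structure(list(mode = "random"), class = "orientation_law")
}

#' @export
print.orientation_law <- function(x, ...) {
  cat("<orientation_law> mode:", x$mode, "\n")
  invisible(x)
}
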