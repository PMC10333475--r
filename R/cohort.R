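# Cohort synthesis from published per-group (mean, SEM, n) summaries.

#' Per-group summary of one cohort
#'
#' Holds the group label, size, and per-variable `(mean, sem)` pairs.  The
#' within-group standard deviation is derived as `sd = sem * sqrt(n)`; the
#' published dispersion column is interpreted as the standard error of the
#' mean (this interpretation is the one under which the published group test
#' statistics reproduce; see the methods vignette).
#'
#' @param label Group label ("gothic", "crenel" or "romanesque").
#' @param n Group size (>= 1).
#' @param variables Named list; each element `c(mean = , sem = )`.
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(label, n, variables) {
  stopifnot(is.character(label), length(label) == 1L)
  stopifnot_scalar_num(n, "n", 1)
  stopifnot(is.list(variables), length(variables) > 0,
            !is.null(names(variables)))
  vars <- lapply(variables, function(v) {
    v <- unlist(v)
    if (!all(c("mean", "sem") %in% names(v)))
      stop("each variable needs `mean` and `sem`", call. = FALSE)
    if (v[["sem"]] < 0) stop("`sem` must be >= 0", call. = FALSE)
    c(mean = unname(v[["mean"]]), sem = unname(v[["sem"]]))
  })
  structure(list(label = label, n = as.integer(n), variables = vars),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s (n = %d)\n", x$label, x$n))
  for (nm in names(x$variables))
    cat(sprintf("  %-8s %.4f +/- %.4f (SEM)\n", nm,
                x$variables[[nm]][["mean"]], x$variables[[nm]][["sem"]]))
  invisible(x)
}

#' Published three-group arch-morphology summaries
#'
#' The per-group (mean, SEM) summaries and group sizes (27 gothic, 25 crenel,
#' 43 romanesque) of the CoA cohort's clinical and CTA morphometric
#' variables, as shipped in `inst/extdata/cohort_summaries.yaml`.
#'
#' @return A named list of three [group_summary()] objects.
#' @export
table1_summaries <- function() {
  path <- system.file("extdata", "cohort_summaries.yaml",
                      package = "coarckit", mustWork = TRUE)
  read_cohort_summaries(path)
}

#' Read cohort summaries from a YAML file
#'
#' Expected layout: `groups: {label: {n: ..., variables: {name: {mean, sem}}}}`.
#'
#' @param path YAML file path.
#' @return Named list of [group_summary()] objects.
#' @export
read_cohort_summaries <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$groups))
  out <- lapply(names(y$groups), function(lbl) {
    g <- y$groups[[lbl]]
    group_summary(lbl, g$n,
                  lapply(g$variables, function(v) c(mean = v$mean,
                                                    sem = v$sem)))
  })
  stats::setNames(out, names(y$groups))
}

#' Sample a synthetic cohort of arch parameter sets
#'
#' For each group, draws `n` cases with every summarised variable distributed
#' as `Normal(mean, sd = sem * sqrt(n))`, truncated to its feasible range
#' (positive ratios, AAO-DAO in (0, 90), TAO-DAO in (90, 180)), and converts
#' each draw to an [arch_params()] set: `height_A = A_T * width`, level
#' diameters `Di = (Di/AOA) * AOA`.  The coarctation of a sampled case is
#' carried by its small D3 (the drawn `D3_AOA` is a measured, stenosed
#' caliber), so `stenosis_severity` is left at 0.  Clinical draws (age,
#' weight, PSPG) and the group label are attached as attributes.
#'
#' @param summaries List of [group_summary()] objects (e.g.
#'   [table1_summaries()]).
#' @param seed Integer seed; the same seed reproduces the same cohort.
#' @param width_T Arch width assigned to every case, mm.
#' @param aoa Ascending-aorta diameter assigned to every case, mm.
#' @return A list of `arch_params`, one per case, with attributes
#'   `group`, `age`, `weight`, `pspg` on each element.
#' @export
sample_cohort <- function(summaries, seed = 1L, width_T = 50, aoa = 12) {
  stopifnot(all(vapply(summaries, inherits, logical(1), "group_summary")))
  with_seed(child_seed(seed, "cohort"), {
    out <- list()
    for (g in summaries) {
      for (i in seq_len(g$n)) {
        p <- NULL
        d0 <- sample_group_draws(g, 1)[1, ]
        for (try_i in 1:100) {
          # feasibility only constrains the chord angles jointly with the
          # shape; on an infeasible combination redraw the two angles alone
          # so the A/T and diameter-ratio marginals stay untruncated
          d <- d0
          if (try_i > 1) {
            redraw <- sample_group_draws(g, 1)[1, ]
            d[c("AAO_DAO", "TAO_DAO")] <- redraw[c("AAO_DAO", "TAO_DAO")]
          }
          ld <- c(AOA = aoa,
                  D1 = unname(d["D1_AOA"]) * aoa,
                  D2 = unname(d["D2_AOA"]) * aoa,
                  D3 = unname(d["D3_AOA"]) * aoa,
                  D4 = unname(d["D4_AOA"]) * aoa,
                  D5 = unname(d["D5_AOA"]) * aoa)
          # the limb split is a free construction parameter: scan it per
          # case so that as many drawn (A/T, AAO-DAO, TAO-DAO) triplets as
          # possible are realisable before resorting to redrawing
          for (split in c(0.5, 0.35, 0.25, 0.15, 0.1, 0.65, 0.75)) {
            cand <- arch_params(arch_type = g$label,
                                height_A = unname(d["A_T"]) * width_T,
                                width_T = width_T,
                                aao_dao_angle = unname(d["AAO_DAO"]),
                                tao_dao_angle = unname(d["TAO_DAO"]),
                                level_diameters = ld,
                                stenosis_severity = 0,
                                limb_split = split,
                                seed = seed)
            ok <- !inherits(try(build_arch(cand, ds = 5), silent = TRUE),
                            "try-error")
            if (ok) { p <- cand; break }
          }
          if (!is.null(p)) break
        }
        if (is.null(p))
          stop("could not draw a feasible case for group ", g$label,
               call. = FALSE)
        attr(p, "group") <- g$label
        for (nm in c("age", "weight", "pspg"))
          if (nm %in% names(d)) attr(p, nm) <- unname(d[nm])
        out[[length(out) + 1L]] <- p
      }
    }
    out
  })
}

# Truncation bounds per variable; draws outside are redrawn.
var_bounds <- function(nm) {
  switch(nm,
         AAO_DAO = c(1, 89),
         TAO_DAO = c(91, 179),
         A_T = c(0.05, 3),
         age = c(0.01, Inf),
         weight = c(0.1, Inf),
         pspg = c(0, Inf),
         c(0.02, Inf))  # diameter ratios and anything else: positive
}

sample_group_draws <- function(g, n = g$n) {
  vars <- names(g$variables)
  m <- matrix(NA_real_, nrow = n, ncol = length(vars),
              dimnames = list(NULL, vars))
  for (nm in vars) {
    mu <- g$variables[[nm]][["mean"]]
    sdv <- g$variables[[nm]][["sem"]] * sqrt(g$n)
    b <- var_bounds(nm)
    x <- stats::rnorm(n, mu, sdv)
    bad <- which(x < b[1] | x > b[2])
    tries <- 0L
    while (length(bad) && tries < 1000L) {
      x[bad] <- stats::rnorm(length(bad), mu, sdv)
      bad <- which(x < b[1] | x > b[2])
      tries <- tries + 1L
    }
    if (length(bad))
      x[bad] <- pmin(pmax(mu, b[1]), b[2])
    m[, nm] <- x
  }
  m
}
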