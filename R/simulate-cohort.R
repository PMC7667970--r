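#' Describe one experimental group of a simulated cohort
#'
#' @param name Group label (e.g. `"lean"`, `"ob/ob"`).
#' @param n Number of mice (>= 2).
#' @param mucus A [mucus_model()] for the group.
#' @param body_weight,glucose,insulin Length-2 vectors `c(mean, sd)` of the
#'   metabolic covariates: body weight in g, fasting glucose in mM, fasting
#'   insulin in µU/ml.
#' @param growth_rate Length-2 `c(mean, sd)` of the mucus growth rate,
#'   µm/min.
#' @param initial_thickness Length-2 `c(mean, sd)` of the initial ex vivo
#'   mucus thickness, µm.
#' @return A `cohort_group` list.
#' @export
cohort_group <- function(name, n, mucus, body_weight, glucose, insulin,
                         growth_rate, initial_thickness) {
  n <- check_count(n, "n", min = 2L)
  stopifnot(inherits(mucus, "mucus_model"))
  for (nm in c("body_weight", "glucose", "insulin", "growth_rate", "initial_thickness")) {
    v <- get(nm)
    if (length(v) != 2 || any(!is.finite(v)) || v[2] < 0) {
      abort_config(sprintf("`%s` must be c(mean, sd) with sd >= 0", nm))
    }
  }
  if (body_weight[1] <= 0 || glucose[1] <= 0 || insulin[1] <= 0 ||
      initial_thickness[1] <= 0) {
    abort_config("covariate and thickness means must be positive")
  }
  structure(
    list(name = name, n = n, mucus = mucus,
         body_weight = body_weight, glucose = glucose, insulin = insulin,
         growth_rate = growth_rate, initial_thickness = initial_thickness),
    class = "cohort_group"
  )
}

#' Configure a simulated two-group mouse cohort
#'
#' Bundles two [cohort_group()] definitions with the housing scenario and the
#' per-mouse sampling plan. Under co-housing, microbiota exchange makes the
#' mucus phenotypes of the two genotypes converge while the metabolic
#' covariates remain genotype-specific; this is modelled by pulling each
#' group's mucus parameters (penetration fraction, layer thickness, growth
#' rate and initial thickness means) towards the across-group mean by the
#' factor `convergence` (1 = full convergence, the default for cohoused
#' scenarios; 0 = none).
#'
#' @param groups List of exactly two [cohort_group()] objects.
#' @param housing `"separated"` or `"cohoused"`.
#' @param convergence Convergence factor in `[0, 1]` applied to the mucus
#'   parameters when `housing = "cohoused"`.
#' @param n_stacks Confocal z-stacks per mouse (default 3).
#' @param n_beads Beads per stack (default 300).
#' @param thickness_noise Measurement noise SD of the thickness series, µm
#'   (default 10).
#' @param times Thickness measurement times, minutes.
#' @param n_locations Probed locations per time point (default 5).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(groups, housing = c("separated", "cohoused"),
                          convergence = 1, n_stacks = 3, n_beads = 300,
                          thickness_noise = 10, times = c(0, 15, 30, 45),
                          n_locations = 5) {
  housing <- match.arg(housing)
  if (length(groups) != 2 || !all(vapply(groups, inherits, TRUE, "cohort_group"))) {
    abort_config("`groups` must be a list of exactly two cohort_group objects")
  }
  check_number(convergence, "convergence", lower = 0, upper = 1)
  structure(
    list(groups = groups, housing = housing, convergence = convergence,
         n_stacks = check_count(n_stacks, "n_stacks"),
         n_beads = check_count(n_beads, "n_beads"),
         thickness_noise = thickness_noise, times = times,
         n_locations = n_locations),
    class = "cohort_config"
  )
}

#' Packaged demo cohort: lean vs genetically obese (ob/ob) littermates
#'
#' The study conditions used throughout the package's own validation: ten
#' mice per genotype; obese mice roughly twice as heavy, with modestly raised
#' fasting glucose and strongly raised fasting insulin (hence HOMA-IR); a
#' more penetrable, thinner, slower-growing colonic mucus layer in the obese
#' group. Under `housing = "cohoused"` the mucus parameters of both
#' genotypes converge to their common mean (microbiota exchange), while the
#' metabolic covariates stay genotype-specific.
#'
#' @param housing `"separated"` (default) or `"cohoused"`.
#' @param n_per_group Mice per genotype (default 10).
#' @return A [cohort_config()].
#' @export
cohort_config_obob <- function(housing = c("separated", "cohoused"),
                               n_per_group = 10) {
  housing <- match.arg(housing)
  lean <- cohort_group(
    "lean", n_per_group,
    mucus = mucus_model(thickness = 80, penetration = 0.1),
    body_weight = c(30, 3), glucose = c(8, 1), insulin = c(15, 5),
    growth_rate = c(2.0, 0.3), initial_thickness = c(450, 30)
  )
  ob <- cohort_group(
    "ob/ob", n_per_group,
    mucus = mucus_model(thickness = 60, penetration = 0.7),
    body_weight = c(55, 5), glucose = c(10, 1.5), insulin = c(60, 15),
    growth_rate = c(1.0, 0.3), initial_thickness = c(350, 30)
  )
  cohort_config(list(lean, ob), housing = housing)
}

#' Packaged demo cohort: normoglycemic vs diabetic NOD mice
#'
#' Seven mice per group; diabetic animals have postprandial glucose above the
#' 14.5 mM screening threshold, similar body weight (weight-matched), and a
#' more penetrable, slower-growing colonic mucus layer.
#'
#' @param n_per_group Mice per group (default 7).
#' @return A [cohort_config()].
#' @export
cohort_config_nod <- function(n_per_group = 7) {
  normo <- cohort_group(
    "normoglycemic", n_per_group,
    mucus = mucus_model(thickness = 80, penetration = 0.15),
    body_weight = c(25, 2), glucose = c(8, 1.5), insulin = c(12, 4),
    growth_rate = c(1.8, 0.3), initial_thickness = c(430, 30)
  )
  diab <- cohort_group(
    "diabetic", n_per_group,
    mucus = mucus_model(thickness = 65, penetration = 0.5),
    body_weight = c(24, 2), glucose = c(20, 3), insulin = c(8, 3),
    growth_rate = c(1.0, 0.3), initial_thickness = c(360, 30)
  )
  cohort_config(list(normo, diab), housing = "separated")
}

# effective per-group mucus/kinetics parameters after housing convergence
effective_groups <- function(cfg) {
  gs <- cfg$groups
  if (cfg$housing != "cohoused" || cfg$convergence == 0) return(gs)
  w <- cfg$convergence
  mean2 <- function(f) mean(vapply(gs, f, numeric(1)))
  p_bar <- mean2(function(g) g$mucus$penetration)
  t_bar <- mean2(function(g) g$mucus$thickness)
  r_bar <- mean2(function(g) g$growth_rate[1])
  i_bar <- mean2(function(g) g$initial_thickness[1])
  lapply(gs, function(g) {
    g$mucus$penetration <- (1 - w) * g$mucus$penetration + w * p_bar
    g$mucus$thickness <- (1 - w) * g$mucus$thickness + w * t_bar
    g$growth_rate[1] <- (1 - w) * g$growth_rate[1] + w * r_bar
    g$initial_thickness[1] <- (1 - w) * g$initial_thickness[1] + w * i_bar
    g
  })
}

#' Simulate a full two-group mouse cohort with ground truth
#'
#' Draws per-mouse metabolic covariates from each group's distributions and
#' generates the mucus data (per-stack bead distance sets and the ex vivo
#' thickness series) from each group's effective mucus model — which, under
#' co-housing, is the converged model shared by both genotypes. All values
#' derive deterministically from `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A `mucus_cohort` list with tibbles:
#'   * `cohort` — one row per mouse: id, group, housing, covariates, HOMA-IR,
#'     and the true (effective) mucus parameters used for that mouse;
#'   * `bead_distances` — `mouse`, `stack`, `d_um` tissue-to-bead distances;
#'   * `thickness` — `mouse`, `location`, `time_min`, `thickness_um`.
#' @examples
#' coh <- simulate_cohort(cohort_config_obob(), seed = 1)
#' head(coh$cohort)
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  eff <- effective_groups(config)

  draw_pos <- function(n, ms) pmax(stats::rnorm(n, ms[1], ms[2]), 0.05 * ms[1])

  with_seed(seed, {
    mice <- purrr::imap(eff, function(g, gi) {
      ids <- sprintf("%s_%02d", gsub("[^[:alnum:]]+", "_", g$name), seq_len(g$n))
      glucose <- draw_pos(g$n, g$glucose)
      insulin <- draw_pos(g$n, g$insulin)
      tibble::tibble(
        mouse = ids,
        group = g$name,
        housing = config$housing,
        body_weight_g = draw_pos(g$n, g$body_weight),
        fasting_glucose_mM = glucose,
        fasting_insulin_uU_ml = insulin,
        homa_ir = homa_ir(glucose, insulin),
        rate_true_um_min = stats::rnorm(g$n, g$growth_rate[1], g$growth_rate[2]),
        t0_true_um = draw_pos(g$n, g$initial_thickness),
        penetration_true = g$mucus$penetration,
        thickness_true_um = g$mucus$thickness
      )
    })
    cohort <- dplyr::bind_rows(mice)

    models <- stats::setNames(
      rep(lapply(eff, function(g) g$mucus), vapply(eff, function(g) g$n, 1L)),
      cohort$mouse
    )

    bead_distances <- purrr::map_dfr(cohort$mouse, function(id) {
      m <- models[[id]]
      purrr::map_dfr(seq_len(config$n_stacks), function(s) {
        dd <- draw_depths(m, config$n_beads)
        tibble::tibble(mouse = id, stack = s, d_um = m$thickness - dd$depth)
      })
    })

    thickness <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
      simulate_thickness_series(
        t0 = cohort$t0_true_um[i], rate = cohort$rate_true_um_min[i],
        noise_sigma = config$thickness_noise, times = config$times,
        n_locations = config$n_locations, mouse = cohort$mouse[i]
      )
    })

    structure(
      list(cohort = cohort, bead_distances = bead_distances,
           thickness = thickness, config = config),
      class = "mucus_cohort"
    )
  })
}

#' @export
print.mucus_cohort <- function(x, ...) {
  cat(sprintf(
    "<mucus_cohort> %d mice (%s), %d bead distances, %d thickness measurements\n",
    nrow(x$cohort), paste(unique(x$cohort$group), collapse = " vs "),
    nrow(x$bead_distances), nrow(x$thickness)
  ))
  invisible(x)
}
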