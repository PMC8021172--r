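#' Cellular-automata configuration
#'
#' @param filter_size odd neighbourhood filter edge (>= 3); default 5,
#'   i.e. a 5 x 5 window.
#' @param cycles number of allocation cycles the demand is spread over
#'   (default 10).
#' @param seed integer seed for the random tie-break key.
#' @param demand_tolerance acceptable relative deviation of the realised
#'   class area from its demand (default 0.005, i.e. 0.5%).
#' @return an object of class `ca_config`.
#' @export
ca_config <- function(filter_size = 5L, cycles = 10L, seed = 1L,
                      demand_tolerance = 0.005) {
  filter_size <- as.integer(filter_size)
  if (filter_size < 3L || filter_size %% 2L == 0L)
    stop("filter_size must be an odd integer >= 3")
  if (cycles < 1L) stop("cycles must be >= 1")
  structure(list(filter_size = filter_size, cycles = as.integer(cycles),
                 seed = as.integer(seed),
                 demand_tolerance = as.numeric(demand_tolerance)),
            class = "ca_config")
}

#' Policy scenario configuration
#'
#' Encodes a land-use policy storyline as data: per-class annual growth
#' rates or absolute area targets, transitions the scenario forbids, and
#' classes whose area may not decrease. The three packaged scenarios are
#' fast urban growth (urban land expanding 5.68%/yr, its observed rate
#' during rapid urbanisation), farmland conservation (urban growth slowed
#' to 1.45%/yr, the urban population growth rate, farmland protected) and
#' ecological conservation (urban growth halted, woodland/grassland/water
#' protected).
#'
#' @param name scenario identifier.
#' @param rates named list/vector, class name -> annual growth rate in
#'   %/yr (negative = decline), compounded over the horizon.
#' @param targets named list/vector, class name -> absolute target area
#'   (km^2), overriding any rate.
#' @param forbidden list of length-2 character vectors `c(from, to)` of
#'   class names whose transition is disallowed.
#' @param protected character vector of class names whose area may not
#'   decrease.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(name, rates = list(), targets = list(),
                            forbidden = list(), protected = character()) {
  rates <- unlist(rates)
  targets <- unlist(targets)
  if (length(rates) && (is.null(names(rates)) || !all(is.finite(rates))))
    stop("rates must be finite and named by class")
  if (length(targets) && is.null(names(targets)))
    stop("targets must be named by class")
  forbidden <- lapply(forbidden, function(p) {
    p <- as.character(unlist(p))
    if (length(p) != 2L) stop("forbidden entries must be (from, to) pairs")
    p
  })
  structure(list(name = name, rates = rates, targets = targets,
                 forbidden = forbidden, protected = as.character(protected)),
            class = "scenario_config")
}

#' Read / write a scenario YAML
#'
#' The YAML schema mirrors [scenario_config()]: `name`, `rates` (class ->
#' %/yr), `targets` (class -> km^2), `forbidden` (list of `[from, to]`),
#' `protected` (list of classes).
#'
#' @param path YAML file path.
#' @return `read_scenario()` returns a `scenario_config`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  scenario_config(y$name %||% tools::file_path_sans_ext(basename(path)),
                  rates = y$rates %||% list(),
                  targets = y$targets %||% list(),
                  forbidden = y$forbidden %||% list(),
                  protected = unlist(y$protected) %||% character())
}

#' @rdname read_scenario
#' @param scenario a `scenario_config`.
#' @export
write_scenario <- function(scenario, path) {
  yaml::write_yaml(list(name = scenario$name,
                        rates = as.list(scenario$rates),
                        targets = as.list(scenario$targets),
                        forbidden = scenario$forbidden,
                        protected = scenario$protected),
                   path)
  invisible(path)
}

#' Scenario demand: target class areas at the horizon year
#'
#' Turns a scenario storyline into per-class target areas. Rate-driven
#' classes compound annually (`a * (1 + r/100)^horizon`), area-targeted
#' classes are set directly, and the residual map area is shared among the
#' unconstrained classes in proportion to their one-or-more-step Markov
#' projection. Protected classes are clamped to be non-decreasing, with
#' the slack re-balanced over the remaining unconstrained classes. Total
#' area is conserved exactly; demands exceeding the map area are rescaled
#' proportionally with a warning, and an error is raised if no feasible
#' assignment remains.
#'
#' @param state current [class_areas()].
#' @param scenario a [scenario_config()].
#' @param horizon projection horizon in years (> 0).
#' @param tm a [transition_matrix()] used for the residual allocation.
#' @return a `class_areas` of demanded areas.
#' @export
scenario_demands <- function(state, scenario, horizon, tm) {
  if (horizon <= 0) stop("horizon must be > 0")
  nm <- state$names
  a0 <- state$areas
  total <- sum(a0)
  bad <- setdiff(c(names(scenario$rates), names(scenario$targets),
                   scenario$protected), nm)
  if (length(bad)) stop("scenario references unknown class(es): ",
                        paste(bad, collapse = ", "))
  target <- setNames(rep(NA_real_, length(nm)), nm)
  for (cls in names(scenario$rates))
    target[cls] <- a0[cls] * (1 + scenario$rates[[cls]] / 100)^horizon
  for (cls in names(scenario$targets))
    target[cls] <- scenario$targets[[cls]]
  constrained <- !is.na(target)
  # protected classes never shrink, including rate/target-driven ones
  prot <- nm %in% scenario$protected
  target[constrained & prot] <- pmax(target[constrained & prot],
                                     a0[constrained & prot])
  if (sum(target[constrained]) > total) {
    warning("scenario demands exceed map area; rescaling proportionally")
    target[constrained] <- target[constrained] * total / sum(target[constrained])
    if (any(prot & constrained & target < a0 - 1e-9))
      stop("infeasible demands: protected class cannot keep its area")
  }
  residual <- total - sum(target[constrained])
  pool <- which(!constrained)
  if (length(pool) == 0L) {
    if (abs(residual) > 1e-6 * total)
      stop("infeasible demands: constrained areas do not sum to the map area")
  } else {
    steps <- max(1L, as.integer(round(horizon / tm$interval)))
    proj <- project_areas(state, tm, steps)$areas
    repeat {
      w <- proj[pool]
      if (sum(w) <= 0) w <- rep(1, length(pool))
      target[pool] <- residual * w / sum(w)
      viol <- pool[prot[pool] & target[pool] < a0[pool] - 1e-9]
      if (!length(viol)) break
      target[viol] <- a0[viol]
      residual <- residual - sum(a0[viol])
      pool <- setdiff(pool, viol)
      if (!length(pool)) {
        if (abs(residual) > 1e-6 * total)
          stop("infeasible demands: protected classes exceed available area")
        break
      }
      if (residual < -1e-9)
        stop("infeasible demands: protected classes exceed available area")
    }
  }
  if (any(target < -1e-9)) stop("infeasible demands: negative target area")
  new_class_areas(state$classes, nm, pmax(target, 0),
                  label = paste0(scenario$name, " +", horizon, "yr"))
}

#' Neighbourhood density of a class
#'
#' Fraction of cells carrying `class_code` within a centred odd-sized
#' square window (the CA neighbourhood filter), truncated and renormalised
#' at the grid edge. Nodata cells count as "not the class" but remain in
#' the window denominator.
#'
#' @param lu a [land_grid()].
#' @param class_code class whose density is measured.
#' @param filter_size odd window edge (default 5).
#' @return a [cont_grid()] of densities in `[0, 1]`.
#' @export
neighborhood_density <- function(lu, class_code, filter_size = 5L) {
  filter_size <- as.integer(filter_size)
  if (filter_size %% 2L == 0L || filter_size < 1L)
    stop("filter_size must be odd")
  ind <- matrix(0, nrow(lu$values), ncol(lu$values))
  ind[!is.na(lu$values) & lu$values == as.integer(class_code)] <- 1
  num <- box_sum(ind, filter_size)
  den <- box_sum(matrix(1, nrow(ind), ncol(ind)), filter_size)
  cont_grid(num / den, lu$cell_size, lu$origin)
}

#' Kappa agreement between two categorical maps
#'
#' Chance-corrected agreement `(P_o - P_c) / (P_p - P_c)` with `P_o` the
#' observed fraction of matching cells, `P_c` the chance agreement implied
#' by the two maps' marginal class proportions and `P_p = 1` (perfect
#' agreement). Values near 1 indicate excellent simulation accuracy;
#' values near 0, agreement no better than chance. Nodata cells (either
#' map) are excluded.
#'
#' @param map_a,map_b aligned [land_grid()]s with the same legend.
#' @return kappa coefficient (<= 1).
#' @export
kappa <- function(map_a, map_b) {
  assert_aligned(map_a, map_b)
  if (!same_legend(map_a$legend, map_b$legend)) stop("legend mismatch")
  ok <- !is.na(map_a$values) & !is.na(map_b$values)
  if (!any(ok)) stop("no jointly valid cells")
  a <- map_a$values[ok]; b <- map_b$values[ok]
  po <- mean(a == b)
  codes <- map_a$legend$codes
  pa <- tabulate(match(a, codes), length(codes)) / length(a)
  pb <- tabulate(match(b, codes), length(codes)) / length(b)
  pc <- sum(pa * pb)
  if (abs(1 - pc) < 1e-15) return(1) # both maps a single identical class
  (po - pc) / (1 - pc)
}

#' Allocate demanded class areas in space (CA step)
#'
#' Produces the projected land-use map by converting cells until each
#' class's area matches its demand. Demands are translated to whole-cell
#' targets (largest-remainder rounding). Each cycle, classes still short
#' of their target are processed in order of decreasing relative
#' shortfall; each takes its per-cycle quota of cells from classes holding
#' a surplus, choosing the eligible cells with the highest score
#' `suitability x neighbourhood density` (ties broken by a seeded random
#' key). A cell may convert `i -> j` only if the transition matrix allows
#' it (`p_ij > 0`) and the scenario does not forbid it; cells of a class
#' at or below its target are never taken, which also enforces protected
#' (non-decreasing) classes. Residual shortfalls after the configured
#' cycles are resolved by extra passes; if constraints block a demand
#' beyond the configured tolerance the blocking class is reported.
#'
#' @param lu_start starting [land_grid()].
#' @param demands [class_areas()] of demanded areas (classes must belong
#'   to the legend; classes without a demand keep their current area).
#' @param atlas a [suitability_atlas()] with a layer per growing class.
#' @param tm a [transition_matrix()] providing the conversion rules.
#' @param scenario optional [scenario_config()] with forbidden pairs.
#' @param config a [ca_config()].
#' @return the simulated [land_grid()]; deterministic given `config$seed`.
#' @export
simulate_landuse <- function(lu_start, demands, atlas, tm, scenario = NULL,
                             config = ca_config()) {
  legend <- lu_start$legend
  codes <- legend$codes
  if (!all(demands$classes %in% codes))
    stop("demand classes must belong to the grid legend")
  assert_aligned(c(list(lu_start), atlas$layers))
  v <- lu_start$values
  valid <- !is.na(v)
  n_valid <- sum(valid)
  ca <- cell_area_km2(lu_start)

  cur <- tabulate(match(v[valid], codes), length(codes))
  target_real <- cur * ca
  target_real[match(demands$classes, codes)] <- demands$areas
  target <- round_preserve_sum(target_real / ca, total = n_valid)

  # eligibility: tm allows i -> j, scenario does not forbid it
  P <- tm$probabilities[match(codes, tm$classes), match(codes, tm$classes),
                        drop = FALSE]
  allowed <- P > 0
  diag(allowed) <- FALSE
  if (!is.null(scenario)) {
    for (p in scenario$forbidden) {
      allowed[match(legend_code(legend, p[1]), codes),
              match(legend_code(legend, p[2]), codes)] <- FALSE
    }
  }

  tie <- with_seed(config$seed, stats::runif(length(v)))
  tol_cells <- pmax(config$demand_tolerance * target, 0)
  max_passes <- config$cycles + 20L

  for (pass in seq_len(max_passes)) {
    deficit <- target - cur
    growers <- which(deficit > 0L)
    if (!length(growers)) break
    growers <- growers[order(deficit[growers] / pmax(target[growers], 1),
                             decreasing = TRUE)]
    cycles_left <- max(config$cycles - pass + 1L, 1L)
    progress <- FALSE
    for (gi in growers) {
      need_total <- target[gi] - cur[gi]
      if (need_total <= 0L) next
      quota <- ceiling(need_total / cycles_left)
      donors <- which(cur > target & allowed[, gi])
      if (!length(donors)) next
      layer <- atlas$layers[[as.character(codes[gi])]]
      if (is.null(layer))
        stop("atlas has no suitability layer for growing class ", codes[gi])
      dens <- neighborhood_density(
        land_grid(v, lu_start$cell_size, lu_start$origin, legend),
        codes[gi], config$filter_size)
      cand <- which(valid & matrix(v %in% codes[donors], nrow(v), ncol(v)))
      if (!length(cand)) next
      score <- layer$values[cand] * dens$values[cand]
      ord <- cand[order(-score, tie[cand])]
      surplus <- cur - target
      taken <- integer(0)
      for (idx in ord) {
        if (quota <= 0L) break
        ci <- match(v[idx], codes)
        if (surplus[ci] <= 0L) next
        surplus[ci] <- surplus[ci] - 1L
        taken <- c(taken, idx)
        quota <- quota - 1L
      }
      if (length(taken)) {
        from <- match(v[taken], codes)
        v[taken] <- codes[gi]
        cur[gi] <- cur[gi] + length(taken)
        for (ci in unique(from)) cur[ci] <- cur[ci] - sum(from == ci)
        progress <- TRUE
      }
    }
    if (!progress) break
  }

  deficit <- target - cur
  if (any(deficit > tol_cells)) {
    bad <- codes[which(deficit > tol_cells)]
    stop("demands infeasible under transition/forbidden constraints; ",
         "blocked class(es): ",
         paste(legend_name(legend, bad), collapse = ", "))
  }
  land_grid(v, lu_start$cell_size, lu_start$origin, legend)
}
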