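#' PTM candidate table
#'
#' The table of modification types considered when decomposing a mass shift.
#' Each entry has a unique name, a mass in Da (given directly or derived
#' from an elemental composition), and a non-negative integer upper bound on
#' how many copies may occur on one protein molecule.
#'
#' @param name Character vector of unique PTM labels.
#' @param mass Numeric masses in Da (> 0); may be `NA` where `composition`
#'   is given.
#' @param upper_bound Integer upper bounds (`NA` allowed; resolved per query
#'   by [resolve_upper_bounds()]).
#' @param composition Optional list of named element-count vectors; negative
#'   counts are allowed (e.g. a sodium adduct replaces a proton). When
#'   present and `mass` is `NA`, the average mass is computed from it.
#' @param mass_kind `"average"` (default; envelope means track the average
#'   mass) or `"monoisotopic"`.
#' @return A data.frame of class `ptm_table`.
#' @export
ptm_table <- function(name, mass = NA_real_, upper_bound = NA_integer_,
                      composition = NULL,
                      mass_kind = c("average", "monoisotopic")) {
  mass_kind <- match.arg(mass_kind)
  n <- length(name)
  if (anyDuplicated(name)) stop("PTM names must be unique")
  mass <- rep_len(as.numeric(mass), n)
  upper_bound <- rep_len(as.integer(upper_bound), n)
  if (!is.null(composition)) {
    stopifnot(length(composition) == n)
    for (i in seq_len(n)) {
      if (is.na(mass[i]) && !is.null(composition[[i]])) {
        mass[i] <- if (mass_kind == "average") {
          composition_mass(composition[[i]])
        } else {
          composition_monoisotopic_mass(composition[[i]])
        }
      }
    }
  }
  if (anyNA(mass) || any(mass <= 0)) {
    stop("every PTM needs a positive mass (directly or via composition)")
  }
  if (any(!is.na(upper_bound) & upper_bound < 0)) {
    stop("upper bounds must be non-negative")
  }
  out <- data.frame(name = as.character(name), mass = mass,
                    upper_bound = upper_bound,
                    stringsAsFactors = FALSE)
  if (!is.null(composition)) attr(out, "composition") <- composition
  class(out) <- c("ptm_table", "data.frame")
  out
}

#' Default PTM table (nine types)
#'
#' The nine modification types used throughout the examples: the biological
#' modifications phosphorylation (Ph), acetylation (Ac) and mono-/di-/
#' tri-methylation (Me1/Me2/Me3), and the preparation artifacts phosphate
#' adduct (Ph-OH), oxidation (Ox), cysteinylation (Cys) and sodium adduct
#' (Na). Masses are average masses derived from the elemental compositions.
#' Upper bounds are left `NA` and resolved per observed shift.
#'
#' @param mass_kind `"average"` or `"monoisotopic"`.
#' @return A `ptm_table`.
#' @export
default_ptm_table <- function(mass_kind = c("average", "monoisotopic")) {
  comps <- list(
    Ph      = c(H = 1, P = 1, O = 3),
    Ac      = c(C = 2, H = 2, O = 1),
    Me1     = c(C = 1, H = 2),
    Me2     = c(C = 2, H = 4),
    Me3     = c(C = 3, H = 6),
    `Ph-OH` = c(H = 3, P = 1, O = 4),
    Ox      = c(O = 1),
    Cys     = c(C = 3, H = 5, N = 1, O = 2, S = 1),
    Na      = c(Na = 1, H = -1)
  )
  ptm_table(names(comps), composition = comps, mass_kind = match.arg(mass_kind))
}

#' Read a PTM table from CSV/TSV
#'
#' Columns: `name`, and `mass` and/or `composition` (formula string such as
#' `"C2H2O"` or `"Na1H-1"`), optional `upper_bound`.
#'
#' @param path File path (separator sniffed from the extension).
#' @return A `ptm_table`.
#' @export
read_ptm_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  comp <- NULL
  if ("composition" %in% names(df)) {
    comp <- lapply(df$composition, parse_formula)
  }
  ptm_table(df$name,
            mass = if ("mass" %in% names(df)) df$mass else NA_real_,
            upper_bound = if ("upper_bound" %in% names(df)) df$upper_bound else NA,
            composition = comp)
}

#' Parse a chemical formula string
#'
#' @param formula String like `"C2H3NO"` or `"Na1H-1"` (negative counts
#'   allowed).
#' @return Named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)(-?[0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)(-?[0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse formula '", formula, "'")
  }
  el <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  ct <- sub("^[A-Z][a-z]?", "", parts)
  ct <- ifelse(ct == "", "1", ct)
  out <- as.numeric(ct)
  names(out) <- el
  tapply(out, names(out), sum)[unique(el)]
}

#' Resolve per-query upper bounds
#'
#' PTM entries without an explicit upper bound get
#' `floor((obs + eps_max) / mass)` capped at `cap`: no pattern can contain
#' more copies of a modification than fit into the observed shift.
#'
#' @param table A `ptm_table`.
#' @param obs Observed mass shift in Da.
#' @param eps_max Mass tolerance in Da.
#' @param cap Hard cap for derived bounds.
#' @return Integer vector of upper bounds.
#' @export
resolve_upper_bounds <- function(table, obs, eps_max, cap = 10L) {
  ub <- table$upper_bound
  derived <- pmin(pmax(floor((obs + eps_max) / table$mass), 0), cap)
  ifelse(is.na(ub), as.integer(derived), as.integer(ub))
}

#' Inference configuration
#'
#' @param mass_tolerance_ppm Tolerance in ppm; `eps_max` (the maximum
#'   allowed gap between observed and inferred shift) is
#'   `ppm * reference_mass`, i.e. the tolerance is taken relative to the
#'   protein mass that the envelope means carry, not to the shift itself.
#' @param reference_mass Protein reference mass in Da.
#' @param objective One of `"min_ptm"`, `"min_error"`, `"min_both"`.
#' @param laps Number of solutions to enumerate (k best).
#' @param epsilon_step Strictness increment for the error objective in Da.
#' @param score_step Strictness increment for the combined objective.
#' @param p_max Normalizer of the combined objective; `NULL` resolves per
#'   query to `min(sum(upper bounds), 10)`. Ten is the plausible ceiling for
#'   simultaneously occupied modification sites on one molecule; using the
#'   raw sum of bounds (often 50+) would shrink the count term until the
#'   combined objective degenerates into pure error minimization and
#'   high-count patterns with accidentally tiny mass error win.
#' @param ub_cap Cap for derived upper bounds.
#' @param eps_max Override the tolerance directly in Da.
#' @return An `inference_config` list.
#' @export
inference_config <- function(mass_tolerance_ppm = 20, reference_mass = NULL,
                             objective = c("min_both", "min_ptm", "min_error"),
                             laps = 1L, epsilon_step = 1e-4,
                             score_step = 1e-6, p_max = NULL, ub_cap = 10L,
                             eps_max = NULL) {
  objective <- match.arg(objective)
  if (is.null(eps_max)) {
    if (is.null(reference_mass)) {
      stop("provide reference_mass (for ppm-based eps_max) or eps_max")
    }
    eps_max <- mass_tolerance_ppm * 1e-6 * reference_mass
  }
  stopifnot(eps_max > 0, laps >= 1)
  structure(list(mass_tolerance_ppm = mass_tolerance_ppm,
                 reference_mass = reference_mass, objective = objective,
                 laps = as.integer(laps), epsilon_step = epsilon_step,
                 score_step = score_step, p_max = p_max,
                 ub_cap = as.integer(ub_cap), eps_max = eps_max),
            class = "inference_config")
}

.pattern_result <- function(counts, names, masses, obs, p_max = NA_real_,
                            eps_max = NA_real_) {
  inferred <- sum(counts * masses)
  err <- abs(inferred - obs)
  total <- sum(counts)
  score <- if (is.finite(p_max) && is.finite(eps_max)) {
    err / eps_max + total / p_max
  } else {
    NA_real_
  }
  structure(list(counts = stats::setNames(as.integer(counts), names),
                 inferred_mass = inferred, error = err,
                 total_ptms = as.integer(total), combined_score = score),
            class = "ptm_pattern")
}

#' @export
print.ptm_pattern <- function(x, ...) {
  cat(format_pattern(x), sprintf(" (mass %.4f Da, error %.4f Da)\n",
                                 x$inferred_mass, x$error))
  invisible(x)
}

#' Compact label for a PTM pattern
#'
#' @param pattern A `ptm_pattern`.
#' @return String like `"1[Ph-OH]1[Na]"`; `"unmodified"` for the zero
#'   pattern.
#' @export
format_pattern <- function(pattern) {
  nz <- pattern$counts[pattern$counts > 0]
  if (length(nz) == 0) return("unmodified")
  paste0(nz, "[", names(nz), "]", collapse = "")
}

#' Enumerate all feasible PTM patterns (brute force)
#'
#' Exhaustively enumerates every bounded count vector whose inferred mass
#' lies within `eps_max` of the observed shift. This is the reference
#' oracle for the optimization routines; it does no objective-guided
#' pruning.
#'
#' @param obs Observed mass shift in Da.
#' @param table A `ptm_table`.
#' @param eps_max Tolerance in Da.
#' @param ub_cap Cap for derived upper bounds.
#' @param guard Maximum allowed size of the enumeration space
#'   `prod(ub + 1)`.
#' @return List of `ptm_pattern` sorted by (total_ptms, error).
#' @export
enumerate_feasible_patterns <- function(obs, table, eps_max, ub_cap = 10L,
                                        guard = 1e8) {
  ub <- resolve_upper_bounds(table, obs, eps_max, cap = ub_cap)
  if (prod(ub + 1) > guard) {
    stop("enumeration space exceeds guard (", format(prod(ub + 1)),
         " combinations); tighten the upper bounds")
  }
  masses <- table$mass
  n <- length(masses)
  results <- list()
  counts <- integer(n)
  # depth-first enumeration over all bounded vectors; the only pruning is
  # the mass feasibility interval, which cannot exclude a feasible vector
  rem_max <- rev(cumsum(rev(ub * masses)))
  recurse <- function(i, partial) {
    if (i > n) {
      if (abs(partial - obs) <= eps_max) {
        results[[length(results) + 1L]] <<- counts
      }
      return(invisible())
    }
    rm_after <- if (i < n) rem_max[i + 1] else 0
    for (k in 0:ub[i]) {
      s <- partial + k * masses[i]
      if (s > obs + eps_max) break
      if (s + rm_after < obs - eps_max) next
      counts[i] <<- k
      recurse(i + 1L, s)
    }
    counts[i] <<- 0L
  }
  recurse(1L, 0)
  pats <- lapply(results, .pattern_result, names = table$name,
                 masses = masses, obs = obs,
                 p_max = max(min(sum(ub), 10), 1), eps_max = eps_max)
  ord <- order(vapply(pats, `[[`, 0L, "total_ptms"),
               vapply(pats, `[[`, 0, "error"))
  pats[ord]
}

# Per-query combined-objective normalizer (see inference_config docs).
.default_p_max <- function(config, ub) {
  p <- if (is.null(config$p_max)) min(sum(ub), 10) else config$p_max
  max(p, 1)
}

# Branch-and-bound core shared by the three integer programs.
#
# objective_fun(err, total) -> objective value at a leaf
# bound_fun(err_lb, count_so_far, count_lb) -> lower bound for a subtree
# leaf_ok(err, total, score) -> strict-improvement / side constraints
.bb_solve <- function(obs, masses, ub, eps_max, objective_fun, bound_fun,
                      leaf_ok) {
  n <- length(masses)
  ord <- order(-masses)  # branch on heavy PTMs first: tighter mass pruning
  masses <- masses[ord]; ub <- ub[ord]
  rem_max <- c(rev(cumsum(rev(ub * masses))), 0)[-1]
  max_mass <- max(masses)
  incumbent <- NULL
  incumbent_obj <- Inf
  counts <- integer(n)
  recurse <- function(i, partial, total) {
    if (i > n) {
      err <- abs(partial - obs)
      if (err > eps_max) return(invisible())
      obj <- objective_fun(err, total)
      if (obj < incumbent_obj - 1e-12 && leaf_ok(err, total, obj)) {
        incumbent_obj <<- obj
        incumbent <<- counts
      }
      return(invisible())
    }
    rm_after <- rem_max[i]
    for (k in 0:ub[i]) {
      s <- partial + k * masses[i]
      if (s > obs + eps_max) break
      if (s + rm_after < obs - eps_max) next
      # lower bounds over the subtree
      err_lb <- max(0, s - obs - 0, obs - s - rm_after)
      err_lb <- max(0, min(err_lb, Inf))
      cnt_lb <- ceiling(max(0, (obs - eps_max - s)) / max_mass)
      if (bound_fun(err_lb, total + k, cnt_lb) >= incumbent_obj - 1e-12) next
      counts[i] <<- k
      recurse(i + 1L, s, total + k)
      counts[i] <<- 0L
    }
  }
  recurse(1L, 0, 0L)
  if (is.null(incumbent)) return(NULL)
  out <- integer(n)
  out[ord] <- incumbent
  out
}

#' Minimize the number of PTMs
#'
#' Integer program: minimize the total PTM count `P = sum(p_i)` subject to
#' `|m . p - obs| <= eps_max` and `0 <= p_i <= ub_i`. When `previous_p` is
#' given the additional constraint `P >= previous_p + 1` makes the next
#' lap's solution strictly worse, which is how the k best solutions are
#' enumerated.
#'
#' @param obs Observed mass shift in Da.
#' @param table A `ptm_table`.
#' @param config An [inference_config()].
#' @param previous_p Total PTM count of the previous lap's optimum, or
#'   `NULL`.
#' @return A `ptm_pattern` with `objective` attribute, or `NULL` when
#'   infeasible.
#' @export
solve_min_ptm <- function(obs, table, config, previous_p = NULL) {
  ub <- resolve_upper_bounds(table, obs, config$eps_max, config$ub_cap)
  floor_p <- if (is.null(previous_p)) -1L else as.integer(previous_p)
  sol <- .bb_solve(
    obs, table$mass, ub, config$eps_max,
    objective_fun = function(err, total) total,
    bound_fun = function(err_lb, cnt, cnt_lb) max(cnt + cnt_lb, floor_p + 1L),
    leaf_ok = function(err, total, obj) total >= floor_p + 1L)
  if (is.null(sol)) return(NULL)
  out <- .pattern_result(sol, table$name, table$mass, obs,
                         .default_p_max(config, ub), config$eps_max)
  out$objective <- "min_ptm"; out$objective_value <- out$total_ptms
  out
}

#' Minimize the mass error
#'
#' Integer program: minimize `eps = |m . p - obs|` subject to
#' `eps <= eps_max` and the bounds. When `previous_eps` is given the next
#' lap requires `eps >= previous_eps + epsilon_step`.
#'
#' @inheritParams solve_min_ptm
#' @param previous_eps Error of the previous lap's optimum in Da, or `NULL`.
#' @return A `ptm_pattern` or `NULL` when infeasible.
#' @export
solve_min_error <- function(obs, table, config, previous_eps = NULL) {
  ub <- resolve_upper_bounds(table, obs, config$eps_max, config$ub_cap)
  floor_eps <- if (is.null(previous_eps)) -Inf else
    previous_eps + config$epsilon_step
  sol <- .bb_solve(
    obs, table$mass, ub, config$eps_max,
    objective_fun = function(err, total) err,
    bound_fun = function(err_lb, cnt, cnt_lb) err_lb,
    leaf_ok = function(err, total, obj) err >= floor_eps)
  if (is.null(sol)) return(NULL)
  out <- .pattern_result(sol, table$name, table$mass, obs,
                         .default_p_max(config, ub), config$eps_max)
  out$objective <- "min_error"; out$objective_value <- out$error
  out
}

#' Minimize PTM count and mass error jointly
#'
#' Integer program minimizing the normalized sum
#' `f = eps / eps_max + sum(p_i) / p_max` subject to the tolerance and
#' bounds. When `previous_score` is given the next lap requires
#' `f >= previous_score + score_step`.
#'
#' @inheritParams solve_min_ptm
#' @param previous_score Combined score of the previous lap's optimum, or
#'   `NULL`.
#' @return A `ptm_pattern` or `NULL` when infeasible.
#' @export
solve_min_both <- function(obs, table, config, previous_score = NULL) {
  ub <- resolve_upper_bounds(table, obs, config$eps_max, config$ub_cap)
  p_max <- .default_p_max(config, ub)
  eps_max <- config$eps_max
  floor_score <- if (is.null(previous_score)) -Inf else
    previous_score + config$score_step
  sol <- .bb_solve(
    obs, table$mass, ub, eps_max,
    objective_fun = function(err, total) err / eps_max + total / p_max,
    bound_fun = function(err_lb, cnt, cnt_lb)
      err_lb / eps_max + (cnt + cnt_lb) / p_max,
    leaf_ok = function(err, total, obj) obj >= floor_score)
  if (is.null(sol)) return(NULL)
  out <- .pattern_result(sol, table$name, table$mass, obs, p_max, eps_max)
  out$objective <- "min_both"; out$objective_value <- out$combined_score
  out
}

#' Enumerate the k best PTM patterns
#'
#' Solves the chosen integer program repeatedly ("laps"), each time adding a
#' strict-improvement constraint derived from the previous optimum, so the
#' objective values strictly increase along the list. Stops early when no
#' further feasible pattern exists. Patterns whose objective ties the
#' previous optimum are skipped by construction; `tie_mode = "nogood"`
#' instead excludes only the previously returned count vectors, so
#' equally-good alternatives are enumerated too (an extension beyond the
#' strict-improvement scheme).
#'
#' @param obs Observed mass shift in Da.
#' @param table A `ptm_table`.
#' @param config An [inference_config()] (its `objective` and `laps` are
#'   used).
#' @param tie_mode `"strict"` (default) or `"nogood"`.
#' @return List of up to `laps` `ptm_pattern` objects with strictly
#'   increasing objective values (`"strict"` mode).
#' @export
enumerate_k_solutions <- function(obs, table, config,
                                  tie_mode = c("strict", "nogood")) {
  tie_mode <- match.arg(tie_mode)
  solver <- switch(config$objective,
                   min_ptm = solve_min_ptm,
                   min_error = solve_min_error,
                   min_both = solve_min_both)
  out <- list()
  prev <- NULL
  seen <- list()
  for (lap in seq_len(config$laps)) {
    if (tie_mode == "strict") {
      sol <- solver(obs, table, config, prev)
    } else {
      sol <- .solve_nogood(obs, table, config, seen)
    }
    if (is.null(sol)) break
    out[[length(out) + 1L]] <- sol
    prev <- sol$objective_value
    seen[[length(seen) + 1L]] <- sol$counts
  }
  out
}

# "No-good cut" enumeration: re-solve excluding exact previous solutions.
.solve_nogood <- function(obs, table, config, seen) {
  ub <- resolve_upper_bounds(table, obs, config$eps_max, config$ub_cap)
  p_max <- .default_p_max(config, ub)
  eps_max <- config$eps_max
  obj_fun <- switch(config$objective,
    min_ptm = function(err, total) total,
    min_error = function(err, total) err,
    min_both = function(err, total) err / eps_max + total / p_max)
  bnd_fun <- switch(config$objective,
    min_ptm = function(err_lb, cnt, cnt_lb) cnt + cnt_lb,
    min_error = function(err_lb, cnt, cnt_lb) err_lb,
    min_both = function(err_lb, cnt, cnt_lb)
      err_lb / eps_max + (cnt + cnt_lb) / p_max)
  nm <- table$name
  sol <- .bb_solve(
    obs, table$mass, ub, eps_max, obj_fun, bnd_fun,
    leaf_ok = function(err, total, obj) TRUE)
  # .bb_solve cannot see the counts at the leaf through leaf_ok, so exclude
  # seen vectors by iterating: if the optimum was already returned, forbid it
  # via a wrapper enumeration over the feasible set of equal objective value.
  if (is.null(sol)) return(NULL)
  candidate <- .pattern_result(sol, nm, table$mass, obs, p_max, eps_max)
  if (!any(vapply(seen, function(s) all(s == candidate$counts), TRUE))) {
    candidate$objective <- config$objective
    candidate$objective_value <- switch(config$objective,
      min_ptm = candidate$total_ptms, min_error = candidate$error,
      min_both = candidate$combined_score)
    return(candidate)
  }
  # fall back: enumerate the feasible set and pick the best unseen vector
  pats <- enumerate_feasible_patterns(obs, table, eps_max, config$ub_cap)
  vals <- vapply(pats, function(p) switch(config$objective,
    min_ptm = as.numeric(p$total_ptms), min_error = p$error,
    min_both = p$combined_score), 0)
  for (i in order(vals)) {
    p <- pats[[i]]
    if (!any(vapply(seen, function(s) all(s == p$counts), TRUE))) {
      p$objective <- config$objective
      p$objective_value <- vals[i]
      return(p)
    }
  }
  NULL
}

#' Infer patterns for a table of mass shifts
#'
#' Runs [enumerate_k_solutions()] for each binned shift and each requested
#' objective and returns a long-format report.
#'
#' @param shifts Numeric vector of observed shifts in Da (e.g.
#'   `average_shift` of an aligned table).
#' @param table A `ptm_table`.
#' @param config An [inference_config()].
#' @param objectives Character vector of objectives to run (defaults to the
#'   config's objective).
#' @return data.frame with columns `shift`, `objective`, `lap`, `pattern`,
#'   `inferred_mass`, `error_da`, `error_ppm`, `total_ptms`,
#'   `objective_value`.
#' @export
infer_patterns <- function(shifts, table, config,
                           objectives = config$objective) {
  rows <- list()
  for (obs in shifts) {
    for (obj in objectives) {
      cfg <- config; cfg$objective <- obj
      sols <- enumerate_k_solutions(obs, table, cfg)
      if (length(sols) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          shift = obs, objective = obj, lap = 1L,
          pattern = "no pattern within tolerance",
          inferred_mass = NA_real_, error_da = NA_real_,
          error_ppm = NA_real_, total_ptms = NA_integer_,
          objective_value = NA_real_)
      } else {
        for (k in seq_along(sols)) {
          p <- sols[[k]]
          base <- if (!is.null(config$reference_mass)) {
            config$reference_mass
          } else {
            NA_real_
          }
          rows[[length(rows) + 1L]] <- data.frame(
            shift = obs, objective = obj, lap = k,
            pattern = format_pattern(p),
            inferred_mass = p$inferred_mass, error_da = p$error,
            error_ppm = if (is.na(base)) NA_real_ else p$error / base * 1e6,
            total_ptms = p$total_ptms,
            objective_value = p$objective_value)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
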