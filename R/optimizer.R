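#' Self-learning optimizer configuration
#'
#' @param candidates_per_iteration candidate designs proposed per iteration
#'   (default 10000).
#' @param archive_size number of optimal samples retained (default 100).
#' @param mae_gate convergence gate: the loop stops once every archive
#'   member's |f_cnn - f_fe| is below this value. Take it from the
#'   cross-validation MAE of the trained surrogate.
#' @param max_iterations iteration backstop (default 50).
#' @param mutation_frac fraction of candidates generated by mutating archive
#'   members (after the first iteration) rather than drawn uniformly
#'   (default 0.4); single-site neighbours of the current best verified
#'   design are always included.
#' @param fine_tune if TRUE, the surrogate is briefly retrained on the
#'   FE-verified samples accumulated during the search (default FALSE so the
#'   core loop is reproducible without retraining variance).
#' @param fine_tune_epochs epochs per fine-tuning round (default 5).
#' @param fe_polish if TRUE (default), after the archive satisfies the error
#'   gate the incumbent is refined by an FE-exact single-site descent: near
#'   the optimum the objective differences between neighbouring designs fall
#'   below the surrogate's own error, so the last refinement steps must be
#'   decided by finite elements, not by the surrogate.
#' @param polish_budget maximum FE evaluations spent in the polish phase
#'   (default 2000).
#' @param seed integer seed for candidate generation.
#' @return object of class `optimizer_config`.
#' @export
optimizer_config <- function(candidates_per_iteration = 10000L,
                             archive_size = 100L, mae_gate = 1,
                             max_iterations = 50L, mutation_frac = 0.4,
                             fine_tune = FALSE, fine_tune_epochs = 5L,
                             fe_polish = TRUE, polish_budget = 2000L,
                             seed = 1L) {
  stopifnot(archive_size <= candidates_per_iteration, mae_gate > 0,
            mutation_frac >= 0, mutation_frac <= 1, polish_budget >= 0)
  structure(list(
    candidates_per_iteration = as.integer(candidates_per_iteration),
    archive_size = as.integer(archive_size), mae_gate = mae_gate,
    max_iterations = as.integer(max_iterations),
    mutation_frac = mutation_frac,
    fine_tune = isTRUE(fine_tune),
    fine_tune_epochs = as.integer(fine_tune_epochs),
    fe_polish = isTRUE(fe_polish),
    polish_budget = as.integer(polish_budget),
    seed = as.integer(seed)
  ), class = "optimizer_config")
}

design_key <- function(design) {
  paste(sprintf("%.1f", design_vector(design)), collapse = ",")
}

mutate_design <- function(design, n_sites, levels = c(0.2, 0.4, 0.6)) {
  v <- design_vector(design)
  sites <- sample.int(36, n_sites)
  for (s in sites) {
    alt <- levels[abs(levels - v[s]) > 1e-9]
    v[s] <- sample(alt, 1)
  }
  scaffold_design(v, cell_size = design$cell_size, levels = levels)
}

single_site_neighbours <- function(design, levels = c(0.2, 0.4, 0.6)) {
  v <- design_vector(design)
  out <- list()
  for (s in 1:36) {
    for (alt in levels[abs(levels - v[s]) > 1e-9]) {
      v2 <- v
      v2[s] <- alt
      out[[length(out) + 1L]] <- scaffold_design(
        v2, cell_size = design$cell_size, levels = levels)
    }
  }
  out
}

# Propose `n` candidate designs not present in `seen` (a character set of
# design keys); rejected duplicates are regenerated so the count is exact.
propose_candidates <- function(n, seen, elites, mutation_frac, best = NULL) {
  out <- vector("list", n)
  keys <- character(n)
  got <- 0L
  fixed <- list()
  if (!is.null(best)) fixed <- single_site_neighbours(best)
  pool_i <- 1L
  while (got < n) {
    if (pool_i <= length(fixed)) {
      cand <- fixed[[pool_i]]
      pool_i <- pool_i + 1L
    } else if (length(elites) > 0 && stats::runif(1) < mutation_frac) {
      base <- elites[[sample.int(length(elites), 1)]]
      cand <- mutate_design(base, sample(1:3, 1))
    } else {
      cand <- random_design()
    }
    key <- design_key(cand)
    if (key %in% seen || key %in% keys[seq_len(got)]) next
    got <- got + 1L
    out[[got]] <- cand
    keys[got] <- key
  }
  list(designs = out, keys = keys)
}

#' Self-learning archive-based scaffold optimization
#'
#' Iteratively proposes candidate designs, ranks them with the surrogate,
#' verifies the best entrants by finite elements, and maintains an elitist
#' archive of the best FE-verified designs. Members whose surrogate error
#' |f_cnn - f_fe| is below the cross-validation MAE gate are retained; the
#' loop stops when the maximum archive error falls below the gate or at the
#' iteration backstop. The candidate stream mixes uniform random designs
#' with mutations of archive members and the single-site neighbourhood of
#' the incumbent, which lets the search refine promising designs inside the
#' 3^36 lattice.
#'
#' @param model trained `cnn_model` surrogate, or a function
#'   `f(design_matrices)` returning predicted objective values (e.g. an
#'   exact FE oracle for sanity checks).
#' @param c_target target [elasticity_matrix()].
#' @param config an [optimizer_config()].
#' @param nu_material,pixel_size,e_solid finite element settings.
#' @param verbose print per-iteration progress.
#' @return list with `best` (design, f_fe, elasticity matrix), `archive`
#'   (data frame: key, f_cnn, f_fe, abs_error), `trace` (per-iteration
#'   best f_fe and max archive error), and `iterations`.
#' @export
self_learning_optimize <- function(model, c_target, config,
                                   nu_material = 0.34, pixel_size = 0.2,
                                   e_solid = 113800, verbose = FALSE) {
  stopifnot(inherits(config, "optimizer_config"))
  withr_seed(config$seed, {
    arch <- list() # entries: design, f_cnn, f_fe, cmat
    seen <- character(0)
    trace <- data.frame(iteration = integer(), best_f_fe = numeric(),
                        max_abs_error = numeric(), n_fe_solves = integer())
    pool_designs <- list()
    pool_labels <- NULL

    for (it in seq_len(config$max_iterations)) {
      elites <- lapply(arch, `[[`, "design")
      best_now <- if (length(arch) > 0) arch[[1]]$design else NULL
      cand <- propose_candidates(config$candidates_per_iteration, seen,
                                 elites, config$mutation_frac, best_now)
      mats <- lapply(cand$designs, encode_design)
      pred <- if (is.function(model)) {
        list(f = model(mats))
      } else {
        cnn_predict(model, mats, c_target, nu_material)
      }
      ranking <- order(pred$f, vapply(mats, function(m)
        paste(sprintf("%.1f", m), collapse = ""), character(1)))
      top <- ranking[seq_len(config$archive_size)]

      lab <- fe_label_designs(cand$designs[top], c_target,
                              nu_material = nu_material,
                              pixel_size = pixel_size, e_solid = e_solid)
      entrants <- lapply(seq_along(top), function(k) {
        list(design = cand$designs[[top[k]]],
             key = cand$keys[top[k]],
             f_cnn = pred$f[top[k]], f_fe = lab$f[k],
             cmat = lab$matrices[[k]])
      })
      seen <- c(seen, cand$keys[top])

      # elitist merge: keep the best archive_size by FE-verified objective,
      # plus any member whose surrogate error is within the MAE gate
      merged <- c(arch, entrants)
      ffe <- vapply(merged, `[[`, numeric(1), "f_fe")
      ord <- order(ffe)
      merged <- merged[ord]
      keep <- seq_len(min(config$archive_size, length(merged)))
      err <- vapply(merged, function(e) abs(e$f_cnn - e$f_fe), numeric(1))
      keep <- union(keep, which(err < config$mae_gate))
      keep <- sort(keep)[seq_len(min(config$archive_size, length(keep)))]
      arch <- merged[keep]

      errs <- vapply(arch, function(e) abs(e$f_cnn - e$f_fe), numeric(1))
      trace <- rbind(trace, data.frame(
        iteration = it, best_f_fe = arch[[1]]$f_fe,
        max_abs_error = max(errs), n_fe_solves = length(top)
      ))
      if (verbose) {
        message(sprintf("iter %2d: best f_fe %.6g, max |f_cnn - f_fe| %.4g",
                        it, arch[[1]]$f_fe, max(errs)))
      }

      if (config$fine_tune && !is.function(model)) {
        pool_designs <- c(pool_designs, lapply(entrants, `[[`, "design"))
        cons <- do.call(rbind, lapply(entrants, function(e) {
          cm <- e$cmat
          c(cm$c11, cm$c12, cm$c13, cm$c22, cm$c23, cm$c33)
        }))
        pool_labels <- rbind(pool_labels, cons)
        fl <- list(constants = pool_labels,
                   f = objective_rows(pool_labels, c_target, nu_material))
        model <- cnn_fit(model, lapply(pool_designs, encode_design), fl,
                         c_target, nu_material,
                         epochs = config$fine_tune_epochs,
                         batch_size = min(128L, length(pool_designs)),
                         val_frac = 0.1, seed = config$seed + it,
                         e_solid = e_solid)
      }

      if (max(errs) < config$mae_gate && it > 1) break
    }

    # FE-exact single-site descent from the incumbent: verify every unseen
    # neighbour, move to the best strict improvement, repeat
    n_polish <- 0L
    if (config$fe_polish && config$polish_budget > 0) {
      npx <- as.integer(round(arch[[1]]$design$cell_size * 3 / pixel_size))
      gs <- grid_solver(npx, npx, nu_material, pixel_size)
      repeat {
        inc <- arch[[1]]
        nb <- single_site_neighbours(inc$design)
        keys <- vapply(nb, design_key, character(1))
        fresh <- !(keys %in% seen)
        if (!any(fresh)) break
        nb <- nb[fresh]
        keys <- keys[fresh]
        if (n_polish + length(nb) > config$polish_budget) {
          nb <- nb[seq_len(config$polish_budget - n_polish)]
          keys <- keys[seq_along(nb)]
        }
        if (length(nb) == 0) break
        lab <- fe_label_designs(nb, c_target, nu_material = nu_material,
                                pixel_size = pixel_size, e_solid = e_solid,
                                solver = gs)
        seen <- c(seen, keys)
        n_polish <- n_polish + length(nb)
        j <- which.min(lab$f)
        if (lab$f[j] < inc$f_fe * (1 - 1e-12)) {
          entrant <- list(design = nb[[j]], key = keys[j],
                          f_cnn = NA_real_, f_fe = lab$f[j],
                          cmat = lab$matrices[[j]])
          arch <- c(list(entrant), arch)
          ffe <- vapply(arch, `[[`, numeric(1), "f_fe")
          arch <- arch[order(ffe)][seq_len(min(config$archive_size,
                                               length(arch)))]
        } else {
          break
        }
        if (n_polish >= config$polish_budget) break
      }
    }

    best <- arch[[1]]
    list(
      best = list(design = best$design, f_fe = best$f_fe,
                  elasticity = best$cmat),
      archive = data.frame(
        key = vapply(arch, `[[`, character(1), "key"),
        f_cnn = vapply(arch, `[[`, numeric(1), "f_cnn"),
        f_fe = vapply(arch, `[[`, numeric(1), "f_fe"),
        abs_error = vapply(arch, function(e) abs(e$f_cnn - e$f_fe),
                           numeric(1))
      ),
      trace = trace, iterations = nrow(trace),
      n_polish_evals = n_polish, model = model
    )
  })
}

#' Exhaustive conventional (periodic-cell) baseline
#'
#' FE-evaluates all 81 periodic designs (one repeated cell, four independent
#' wall thicknesses) and returns the exact argmin of the matching objective
#' over that design space.
#'
#' @param c_target target [elasticity_matrix()].
#' @param nu_material,pixel_size,e_solid finite element settings.
#' @return list with `best` (design, f, elasticity) and `table`
#'   (data frame of all 81 designs with their objectives).
#' @export
conventional_optimize <- function(c_target, nu_material = 0.34,
                                  pixel_size = 0.2, e_solid = 113800) {
  designs <- enumerate_periodic()
  lab <- fe_label_designs(designs, c_target, nu_material = nu_material,
                          pixel_size = pixel_size, e_solid = e_solid)
  tab <- data.frame(
    left = vapply(designs, function(d) d$thickness[1, 1, 1], numeric(1)),
    top = vapply(designs, function(d) d$thickness[1, 1, 2], numeric(1)),
    bottom = vapply(designs, function(d) d$thickness[1, 1, 3], numeric(1)),
    right = vapply(designs, function(d) d$thickness[1, 1, 4], numeric(1)),
    f = lab$f
  )
  i <- which.min(lab$f)
  list(best = list(design = designs[[i]], f = lab$f[i],
                   elasticity = lab$matrices[[i]]),
       table = tab)
}

#' Compare the self-learning and conventional design frameworks
#'
#' For each target, runs both optimizers and summarizes the signed relative
#' errors of the four weighted constants (c11, c12, c22, c33) of the
#' returned designs with MIN/Q1/Q2/Q3/MAX/AVG statistics per constant and
#' method.
#'
#' @param targets list of target [elasticity_matrix()] objects.
#' @param model trained `cnn_model`.
#' @param config an [optimizer_config()].
#' @param nu_material,pixel_size,e_solid finite element settings.
#' @return list with `errors` (long data frame of per-target relative
#'   errors) and `summary` (per constant and method).
#' @export
compare_methods <- function(targets, model, config, nu_material = 0.34,
                            pixel_size = 0.2, e_solid = 113800) {
  stopifnot(length(targets) >= 1)
  rows <- list()
  consts <- c("c11", "c12", "c22", "c33")
  for (i in seq_along(targets)) {
    tg <- targets[[i]]
    cfg <- config
    cfg$seed <- config$seed + i
    cnn <- self_learning_optimize(model, tg, cfg, nu_material = nu_material,
                                  pixel_size = pixel_size, e_solid = e_solid)
    conv <- conventional_optimize(tg, nu_material = nu_material,
                                  pixel_size = pixel_size, e_solid = e_solid)
    for (k in consts) {
      rows[[length(rows) + 1L]] <- data.frame(
        target = i, constant = k, method = "cnn",
        re = relative_error(cnn$best$elasticity[[k]], tg[[k]]))
      rows[[length(rows) + 1L]] <- data.frame(
        target = i, constant = k, method = "conventional",
        re = relative_error(conv$best$elasticity[[k]], tg[[k]]))
    }
  }
  errors <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(errors, list(errors$constant,
                                                   errors$method)),
    function(g) {
      qs <- quartile_summary(g$re)
      data.frame(constant = g$constant[1], method = g$method[1],
                 t(unlist(qs)))
    }))
  rownames(summ) <- NULL
  list(errors = errors, summary = summ)
}
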