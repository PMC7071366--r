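# The six-set experiment protocol.
#
# Three classifiers are trained on "noise-free" stimuli (sigma^2 = 0.001
# perturbations, unity context weights): a context-free span-0 model on
# the six isolated target letters, a span-2 model on six 3-letter words,
# and a span-4 model on six 5-letter words. Test conditions then
# manipulate the centre-letter noise level and the congruency of the
# context:
#
#   Set 1  context-free classification (span 0)
#   Set 2  congruent noise-free context (span 2)
#   Set 3  congruent noise-free context (span 4)
#   Set 4A attenuated context, weights 0.7 uniform (span 4)
#   Set 4B decaying context, weights 0.4/0.7 (span 4)
#   Set 5  noisy context, same variance as the centre (span 4)
#   Set 6  flipped (left/right exchanged) context (span 2)
#
# Each condition is scored for ambiguous hybrid centres (resolved to the
# context-implied parent; in Set 1, to either parent) and for the plain
# target letters, over a grid of centre noise variances, averaging over
# independently initialised networks and noise draws (two-stage: per item,
# then across items).

#' Words used to train the span-2 and span-4 classifiers
#'
#' @param span Context span, 2 or 4.
#' @return Character vector of six words whose centre letters are the six
#'   target classes in order A, H, O, U, P, R (span 2) or A, H, U, O, P, R
#'   (span 4).
#' @export
training_words <- function(span) {
  if (span == 2) c("BAG", "THE", "MOW", "FUN", "SPY", "IRK")
  else if (span == 4) c("BEAST", "ETHYL", "FLUID", "GNOME", "IMPLY", "SCREW")
  else stop("training words are defined for spans 2 and 4")
}

#' The standard centre-letter noise grid
#'
#' @return Numeric vector of the nine test noise variances.
#' @export
noise_grid_default <- function() c(0.1, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75, 2)

set_table <- function() {
  data.frame(
    set_id = c("1", "2", "3", "4A", "4B", "5", "6"),
    span = c(0L, 2L, 4L, 4L, 4L, 4L, 2L),
    context_mode = c("none", "congruent", "congruent", "weighted", "weighted",
                     "noisy", "flipped"),
    stringsAsFactors = FALSE
  )
}

set_context_weights <- function(set_id, span) {
  switch(set_id,
         "4A" = c(0.7, 0.7, 1, 0.7, 0.7),
         "4B" = c(0.4, 0.7, 1, 0.7, 0.4),
         rep(1, span + 1))
}

hybrid_for <- function(letter) {
  pair <- switch(letter, A = , H = c("A", "H"), O = , U = c("O", "U"),
                 P = , R = c("P", "R"),
                 stop(sprintf("no ambiguous hybrid covers letter '%s'", letter)))
  make_ambiguous(pair[1], pair[2])
}

#' Specify one experiment set
#'
#' @param set_id One of `"1"`, `"2"`, `"3"`, `"4A"`, `"4B"`, `"5"`, `"6"`.
#' @param center `"ambiguous"` to test hybrid centre letters (the
#'   ambiguity-resolution experiments) or `"target"` to test the plain
#'   target letters.
#' @param n_networks Number of independently initialised networks.
#' @param n_samples Number of noisy test stimuli per item, network and
#'   noise level.
#' @param noise_grid Centre-letter noise variances to test.
#' @param seed Integer seed governing all noise draws of the set.
#' @return An `experiment_spec` object.
#' @export
experiment_spec <- function(set_id, center = c("ambiguous", "target"),
                            n_networks = 5, n_samples = 50,
                            noise_grid = noise_grid_default(), seed = 1L) {
  center <- match.arg(center)
  st <- set_table()
  if (!set_id %in% st$set_id) {
    stop("set_id must be one of ", paste(st$set_id, collapse = ", "))
  }
  if (n_networks < 1 || n_samples < 1) stop("n_networks and n_samples must be >= 1")
  if (any(noise_grid < 0)) stop("noise variances must be >= 0")
  row <- st[st$set_id == set_id, ]
  structure(
    list(set_id = set_id, center = center, span = row$span,
         context_mode = row$context_mode,
         context_weights = set_context_weights(set_id, row$span),
         train_words = if (row$span == 0) target_letters() else training_words(row$span),
         n_networks = as.integer(n_networks), n_samples = as.integer(n_samples),
         noise_grid = noise_grid, seed = as.integer(seed)),
    class = "experiment_spec"
  )
}

# Training set for a given span: exemplars of each class with small
# Gaussian perturbations (sigma^2 = 0.001 by default) applied to the
# target and every context letter, unity weights.
build_training_set <- function(span, samples_per_class, sigma2, seed) {
  cfg <- integration_config(span / 2, span / 2)
  words <- if (span == 0) target_letters() else training_words(span)
  inputs <- vector("list", length(words) * samples_per_class)
  labels <- integer(length(inputs))
  k <- 0L
  for (ci in seq_along(words)) {
    letters_ <- strsplit(words[ci], "")[[1L]]
    glyphs <- lapply(letters_, render_glyph)
    mid <- span / 2 + 1L
    class_idx <- match(letters_[mid], target_letters())
    if (is.na(class_idx)) stop("centre letter is not a target class: ", words[ci])
    for (r in seq_len(samples_per_class)) {
      k <- k + 1L
      noisy <- lapply(seq_along(glyphs), function(j) {
        add_noise(glyphs[[j]], sigma2, seed = derive_seed(seed, "train", ci, r, j))
      })
      left <- if (span > 0) noisy[seq_len(span / 2)] else list()
      right <- if (span > 0) noisy[mid + seq_len(span / 2)] else list()
      inputs[[k]] <- integrate_stimuli(noisy[[mid]], left, right, cfg)
      labels[k] <- class_idx
    }
  }
  list(inputs = inputs, labels = labels)
}

#' Train an ensemble of identically specified networks
#'
#' Trains `n_networks` networks of the standard architecture for the given
#' span, each from its own random initialisation and its own training-set
#' noise draws, on the span's training words (or the isolated target
#' letters for span 0).
#'
#' @param span Context span: 0, 2 or 4.
#' @param n_networks Ensemble size.
#' @param config Base [train_config()]; each network derives its own seed.
#' @param seed Integer ensemble seed.
#' @return List of `trained_network` objects.
#' @export
train_ensemble <- function(span, n_networks = 5, config = train_config(), seed = 1L) {
  spec <- context_net_spec(span)
  lapply(seq_len(n_networks), function(k) {
    net_seed <- derive_seed(seed, "ensemble", span, k)
    ts <- build_training_set(span, config$samples_per_class,
                             config$train_noise_variance, seed = net_seed)
    cfg <- config
    cfg$seed <- net_seed
    train_network(spec, ts$inputs, ts$labels, cfg)
  })
}

#' Score a context-free prediction of an ambiguous stimulus
#'
#' Without context the true class of an ambiguous stimulus is undefined;
#' a prediction counts as correct when it falls in either parent class.
#'
#' @param prediction A `prediction` (or a decided class index).
#' @param parents Character vector of the two parent letters, or their
#'   class indices.
#' @return 1 if the decided class is one of the two parents, else 0.
#' @export
score_ambiguous_contextfree <- function(prediction, parents) {
  decided <- if (inherits(prediction, "prediction")) prediction$decided_class
             else as.integer(prediction)
  if (is.character(parents)) parents <- match(parents, target_letters())
  as.integer(decided %in% parents)
}

#' Score a prediction against the context-implied class
#'
#' In context, the surrounding word implies a unique parent (e.g. the
#' hybrid readable as A or H must be an A inside B_G); only that class
#' counts as correct.
#'
#' @param prediction A `prediction` (or a decided class index).
#' @param implied_class The context-implied letter or class index.
#' @return 1 if the decided class equals the implied class, else 0.
#' @export
score_contextual <- function(prediction, implied_class) {
  decided <- if (inherits(prediction, "prediction")) prediction$decided_class
             else as.integer(prediction)
  if (is.character(implied_class)) implied_class <- match(implied_class, target_letters())
  as.integer(decided == implied_class)
}

# Items of one experiment set: per item the context word actually shown,
# the centre stimulus, the scoring rule and its reference classes.
set_items <- function(spec) {
  tl <- target_letters()
  if (spec$set_id == "1") {
    if (spec$center == "ambiguous") {
      hybrids <- lapply(c("A", "O", "P"), hybrid_for)
      return(lapply(hybrids, function(h) {
        list(item = h$label, word = NA_character_, test_word = NA_character_,
             center = h, rule = "parents", parents = match(h$parents, tl),
             implied = NA_integer_)
      }))
    }
    return(lapply(tl, function(L) {
      list(item = L, word = NA_character_, test_word = NA_character_,
           center = render_glyph(L), rule = "implied", parents = NULL,
           implied = match(L, tl))
    }))
  }
  words <- if (spec$span == 0) target_letters() else training_words(spec$span)
  lapply(words, function(w) {
    letters_ <- strsplit(w, "")[[1L]]
    mid_letter <- letters_[(length(letters_) + 1L) / 2L]
    test_word <- if (spec$context_mode == "flipped") flip_word(w) else w
    center <- if (spec$center == "ambiguous") hybrid_for(mid_letter)
              else render_glyph(mid_letter)
    item <- if (spec$center == "ambiguous") {
      sub(mid_letter, paste0("[", center$label, "]"), test_word, fixed = TRUE)
    } else test_word
    list(item = item, word = w, test_word = test_word, center = center,
         rule = "implied", parents = NULL, implied = match(mid_letter, tl))
  })
}

# Test-time integration config for one set at a given centre noise level:
# the centre slice gets its noise drawn separately (the centre stimulus is
# already noisy), the context slots get noise only in the "noisy" mode.
test_integration_config <- function(spec, sigma2) {
  span <- spec$span
  if (span == 0) return(integration_config(0, 0))
  nv <- rep(0, span + 1)
  if (spec$context_mode == "noisy") {
    nv[-(span / 2 + 1)] <- sigma2
  }
  integration_config(span / 2, span / 2, weights = spec$context_weights,
                     noise_variances = nv)
}

#' Run one experiment set
#'
#' For every network, item and noise level, generates `n_samples` noisy
#' centre stimuli, applies the set's context manipulation, classifies, and
#' scores. Results are averaged per item over networks and samples, then
#' across items (two-stage averaging).
#'
#' @param spec An [experiment_spec()].
#' @param networks Optional pre-trained ensemble for the set's span (see
#'   [train_ensemble()]); trained on demand when omitted.
#' @param train_cfg Base [train_config()] used when training on demand.
#' @param verbose Print progress.
#' @return An `experiment_result`: list with `table` (set, sigma2, mean
#'   probability, Monte Carlo standard error, trial count), `per_item`,
#'   `per_letter` (items pooled by centre stimulus) and `manifest`
#'   (seeds, spans, convergence flags).
#' @export
run_set <- function(spec, networks = NULL, train_cfg = train_config(),
                    verbose = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  if (is.null(networks)) {
    networks <- train_ensemble(spec$span, spec$n_networks, train_cfg,
                               seed = spec$seed)
  }
  if (length(networks) < spec$n_networks) {
    stop("fewer trained networks supplied than n_networks")
  }
  networks <- networks[seq_len(spec$n_networks)]
  bad <- !vapply(networks, function(n) n$converged, logical(1))
  if (any(bad)) {
    thr <- train_cfg$loss_threshold
    worst <- max(vapply(networks, function(n) n$final_loss, numeric(1)))
    if (worst > 10 * thr) {
      warning(sprintf("excluding %d non-convergent network(s) (loss > 10x threshold)",
                      sum(bad)))
      networks <- networks[!bad]
    }
  }
  items <- set_items(spec)
  rows <- list()
  for (k in seq_along(networks)) {
    net <- networks[[k]]
    for (ii in seq_along(items)) {
      it <- items[[ii]]
      ctx_letters <- if (!is.na(it$test_word)) {
        strsplit(it$test_word, "")[[1L]][-(spec$span / 2 + 1L)]
      } else character(0)
      left <- if (spec$span > 0) lapply(ctx_letters[seq_len(spec$span / 2)],
                                        render_glyph) else list()
      right <- if (spec$span > 0) {
        lapply(ctx_letters[spec$span / 2 + seq_len(spec$span / 2)], render_glyph)
      } else list()
      for (si in seq_along(spec$noise_grid)) {
        s2 <- spec$noise_grid[si]
        cfg <- test_integration_config(spec, s2)
        inputs <- lapply(seq_len(spec$n_samples), function(s) {
          ss <- derive_seed(spec$seed, spec$set_id, spec$center, k, ii, si, s)
          center_noisy <- add_noise(it$center, s2, seed = ss)
          integrate_stimuli(center_noisy, left, right, cfg,
                            seed = derive_seed(ss, "ctx"))
        })
        post <- forward_posteriors(net$spec, net$weights, inputs)
        decided <- max.col(post, ties.method = "first")
        score <- if (it$rule == "parents") {
          as.integer(decided %in% it$parents)
        } else {
          as.integer(decided == it$implied)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          set_id = spec$set_id, center = spec$center, network = k,
          item = it$item, center_stimulus = it$center$label, sigma2 = s2,
          probability = mean(score), n = spec$n_samples,
          stringsAsFactors = FALSE)
      }
      if (verbose) {
        message(sprintf("set %s (%s): network %d/%d item %s done",
                        spec$set_id, spec$center, k, length(networks), it$item))
      }
    }
  }
  per_item <- do.call(rbind, rows)
  # stage 1: average each item over networks and samples
  item_means <- stats::aggregate(probability ~ item + sigma2, per_item, mean)
  # stage 2: average across items
  tab <- stats::aggregate(probability ~ sigma2, item_means, mean)
  n_trials <- length(networks) * spec$n_samples * length(items)
  tab$se <- sqrt(pmax(tab$probability * (1 - tab$probability), 0) / n_trials)
  tab$n <- n_trials
  tab <- data.frame(set_id = spec$set_id, center = spec$center, tab,
                    stringsAsFactors = FALSE)
  letter_means <- stats::aggregate(probability ~ center_stimulus + sigma2,
                                   per_item, mean)
  structure(
    list(spec = spec, table = tab[order(tab$sigma2), ],
         per_item = per_item, per_letter = letter_means,
         manifest = list(
           seed = spec$seed, span = spec$span, n_networks = length(networks),
           n_samples = spec$n_samples,
           converged = vapply(networks, function(n) n$converged, logical(1)),
           final_loss = vapply(networks, function(n) n$final_loss, numeric(1)),
           epochs = vapply(networks, function(n) n$epochs, integer(1)))),
    class = "experiment_result"
  )
}

#' Run the complete experiment battery
#'
#' Trains one ensemble per span (0, 2, 4) and evaluates all requested sets
#' for ambiguous and/or target centre stimuli, reusing each ensemble
#' across the sets that share its architecture (Sets 2 and 6 share the
#' span-2 ensemble; Sets 3, 4A, 4B and 5 share the span-4 ensemble).
#'
#' @param seed Global seed; every training and noise stream derives from it.
#' @param profile `"ci"` for the scaled-down protocol (5 networks x 50
#'   samples) or `"full"` for the full averaging protocol (30 networks x
#'   100 samples).
#' @param sets Subset of set ids to run.
#' @param centers One or both of `"ambiguous"`, `"target"`.
#' @param noise_grid Centre noise variances (default the standard grid).
#' @param train_cfg Base [train_config()].
#' @param n_networks,n_samples Override the profile's protocol scale.
#' @param verbose Print progress.
#' @return An `experiment_tables` object: list with `table` (combined tidy
#'   data frame over all sets, centres and noise levels) and `results`
#'   (named list of `experiment_result`).
#' @export
run_all <- function(seed = 1L, profile = c("ci", "full"),
                    sets = c("1", "2", "3", "4A", "4B", "5", "6"),
                    centers = c("ambiguous", "target"),
                    noise_grid = noise_grid_default(),
                    train_cfg = train_config(),
                    n_networks = NULL, n_samples = NULL, verbose = FALSE) {
  profile <- match.arg(profile)
  centers <- match.arg(centers, several.ok = TRUE)
  if (is.null(n_networks)) n_networks <- if (profile == "full") 30L else 5L
  if (is.null(n_samples)) n_samples <- if (profile == "full") 100L else 50L
  st <- set_table()
  spans_needed <- sort(unique(st$span[st$set_id %in% sets]))
  ensembles <- list()
  for (sp in spans_needed) {
    if (verbose) message(sprintf("training %d span-%d networks ...", n_networks, sp))
    ensembles[[as.character(sp)]] <-
      train_ensemble(sp, n_networks, train_cfg, seed = seed)
  }
  results <- list()
  for (ctr in centers) {
    for (sid in sets) {
      spec <- experiment_spec(sid, center = ctr, n_networks = n_networks,
                              n_samples = n_samples, noise_grid = noise_grid,
                              seed = seed)
      key <- paste0("set", sid, "_", ctr)
      if (verbose) message("running ", key, " ...")
      results[[key]] <- run_set(spec, networks = ensembles[[as.character(spec$span)]],
                                train_cfg = train_cfg, verbose = FALSE)
    }
  }
  tab <- do.call(rbind, lapply(results, function(r) r$table))
  rownames(tab) <- NULL
  structure(list(table = tab, results = results, seed = seed,
                 n_networks = n_networks, n_samples = n_samples),
            class = "experiment_tables")
}

#' Matrix view of experiment results
#'
#' @param x An `experiment_tables` object from [run_all()].
#' @param center `"ambiguous"` or `"target"`.
#' @return Numeric matrix, sets as rows, noise variances as columns.
#' @export
result_matrix <- function(x, center = c("ambiguous", "target")) {
  center <- match.arg(center)
  tab <- x$table[x$table$center == center, ]
  sets <- unique(tab$set_id)
  sig <- sort(unique(tab$sigma2))
  m <- matrix(NA_real_, length(sets), length(sig),
              dimnames = list(paste("Set", sets), format(sig)))
  for (i in seq_along(sets)) {
    sub <- tab[tab$set_id == sets[i], ]
    m[i, ] <- sub$probability[match(sig, sub$sigma2)]
  }
  m
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result set %s (%s): %d networks x %d samples>\n",
              x$spec$set_id, x$spec$center, x$manifest$n_networks,
              x$manifest$n_samples))
  print(x$table[, c("sigma2", "probability", "se")], row.names = FALSE)
  invisible(x)
}

#' @export
print.experiment_tables <- function(x, ...) {
  for (ctr in unique(x$table$center)) {
    cat(sprintf("-- %s centre stimuli --\n", ctr))
    print(round(result_matrix(x, ctr), 3))
  }
  invisible(x)
}
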