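## Site-mutability modeling.
##
## A penalized (elastic-net, near-ridge by default) logistic regression of
## mutation presence on genomic features: chromosome, functional class,
## collapsed trinucleotide context, recombination rate, 41-bp G+C content
## and triplet complexity, germline expression, repeat membership,
## chromatin state and A/T-cluster membership. The training set combines
## the observed mutation sites with a large uniform sample of non-mutated
## callable sites; the class imbalance is kept as-is because the predicted
## probabilities are interpreted relatively, not as absolute rates. Odds
## ratios are e^c per coefficient.

#' Compute model features for genomic sites
#'
#' @param genome Annotated `ma_genome`.
#' @param sites Data frame with `chrom`, `pos`.
#' @param catalog Repeat catalog; sites inside a catalogued run get
#'   `repeat_seq = TRUE`.
#' @param width Window width for GC/complexity (default 41 bp).
#' @return Tibble of per-site features.
#' @export
site_features <- function(genome, sites, catalog = NULL, width = 41L) {
  sites <- as_tibble(sites)
  catalog <- catalog %||% detect_repeats(genome)
  ann <- annotate_sites(genome, sites)
  win <- window_stats(genome, sites, width = width)
  rep_map <- map_variant_to_repeat(sites |> select("chrom", "pos"), catalog,
                                   flank = 0L)
  tibble(
    chrom = sites$chrom, pos = sites$pos,
    chromosome = sites$chrom,
    functional_class = ann$functional_class,
    context_triplet = collapse_context(genome, sites),
    recombination_rate = ann$recombination_rate,
    gc = win$gc, complexity = win$S,
    germline_expressed = ann$germline_expressed,
    repeat_seq = rep_map$repeat_status == "in_repeat",
    chromatin_state = ann$chromatin_state,
    at_cluster = ann$at_cluster
  )
}

#' Assemble the mutability training set
#'
#' Combines the unique mutated sites with `n_random` sites drawn uniformly
#' from callable, non-mutated positions (collisions redrawn), computes the
#' identical feature set for both strata and attaches the binary response
#' (1 = mutation).
#'
#' @param genome Annotated `ma_genome`.
#' @param mutations Mutation records with `chrom`, `pos` (typically the
#'   substitution records).
#' @param n_random Number of random non-mutated sites.
#' @param seed Integer seed.
#' @param catalog Repeat catalog (recomputed when `NULL`).
#' @return Feature tibble with a `response` column.
#' @export
build_training_set <- function(genome, mutations, n_random, seed,
                               catalog = NULL) {
  catalog <- catalog %||% detect_repeats(genome)
  mut_sites <- as_tibble(mutations) |> distinct(.data$chrom, .data$pos)
  with_seed(derive_seed(seed, "training"), {
    pools <- site_pools(genome)
    total <- pools$AT$total + pools$GC$total
    draw <- function(k) {
      ka <- rbinom(1L, k, pools$AT$total / total)
      bind_rows(draw_pool_sites(pools$AT, ka), draw_pool_sites(pools$GC, k - ka))
    }
    rand <- draw(n_random) |>
      anti_join(mut_sites, by = c("chrom", "pos")) |>
      distinct(.data$chrom, .data$pos)
    while (nrow(rand) < n_random) {
      rand <- bind_rows(rand, draw(n_random - nrow(rand))) |>
        anti_join(mut_sites, by = c("chrom", "pos")) |>
        distinct(.data$chrom, .data$pos)
    }
    rand <- rand |> head(n_random)
    sites <- bind_rows(mut_sites |> mutate(response = 1L),
                       rand |> mutate(response = 0L))
    feats <- site_features(genome, sites |> select("chrom", "pos"), catalog)
    bind_cols(feats, sites |> select("response"))
  })
}

MUTABILITY_CATEGORICAL <- c("chromosome", "functional_class",
                            "context_triplet", "chromatin_state")
MUTABILITY_NUMERIC <- c("recombination_rate", "gc", "complexity")
MUTABILITY_BINARY <- c("germline_expressed", "repeat_seq", "at_cluster")

## one-hot expansion with a frozen schema; unseen columns are zero-filled
expand_features <- function(feats, schema = NULL) {
  feats <- as_tibble(feats)
  cols <- list()
  for (v in intersect(MUTABILITY_NUMERIC, names(feats))) {
    cols[[v]] <- as.numeric(feats[[v]])
  }
  for (v in intersect(MUTABILITY_BINARY, names(feats))) {
    cols[[v]] <- as.numeric(feats[[v]])
  }
  for (v in intersect(MUTABILITY_CATEGORICAL, names(feats))) {
    lv <- sort(unique(feats[[v]][!is.na(feats[[v]])]))
    for (l in lv) cols[[paste0(v, "=", l)]] <- as.numeric(feats[[v]] == l)
  }
  x <- do.call(cbind, cols)
  x[is.na(x)] <- 0
  if (is.null(schema)) {
    keep <- apply(x, 2, function(cc) stats::var(cc) > 0)
    x <- x[, keep, drop = FALSE]
  } else {
    miss <- setdiff(schema, colnames(x))
    if (length(miss)) {
      x <- cbind(x, matrix(0, nrow(x), length(miss),
                           dimnames = list(NULL, miss)))
    }
    x <- x[, schema, drop = FALSE]
  }
  x
}

#' Fit the penalized logistic mutability model
#'
#' Elastic-net logistic regression (default `alpha = 0.01`, near ridge).
#' When `lambda` is `NULL` it is chosen as the value minimising the k-fold
#' cross-validated deviance (`lambda.min`); separation is harmless because
#' the penalty keeps coefficients finite.
#'
#' @param training Feature tibble with a `response` column (see
#'   [build_training_set()]), or a numeric matrix plus `y`.
#' @param y Response vector when `training` is a matrix.
#' @param alpha Elastic-net mixing parameter.
#' @param lambda Regularization strength; `NULL` selects by
#'   cross-validation.
#' @param nfolds Cross-validation folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return A `mutability_model` with coefficients, odds ratios, the chosen
#'   `lambda`, `alpha`, the feature schema and training composition.
#' @export
fit_penalized_logistic <- function(training, y = NULL, alpha = 0.01,
                                   lambda = NULL, nfolds = 10L, seed = 1L) {
  if (is.matrix(training)) {
    x <- training
    stopifnot(!is.null(y))
    schema <- colnames(x)
  } else {
    training <- as_tibble(training)
    stopifnot("response" %in% names(training))
    y <- training$response
    x <- expand_features(training |> select(-"response"))
    schema <- colnames(x)
  }
  if (length(unique(y)) < 2L) abort("both response classes must be present")
  cv <- NULL
  if (is.null(lambda)) {
    cv <- with_seed(derive_seed(seed, "cv"), {
      glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                        nfolds = nfolds, type.measure = "deviance")
    })
    lambda <- cv$lambda.min
  }
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                        lambda = lambda)
  cf <- as.numeric(coef(fit))
  structure(list(
    intercept = cf[1],
    coefficients = setNames(cf[-1], rownames(coef(fit))[-1]),
    lambda = lambda, alpha = alpha, schema = schema,
    n_mutated = sum(y == 1), n_random = sum(y == 0),
    dev_ratio = fit$dev.ratio, null_deviance = fit$nulldev,
    cv = if (!is.null(cv)) tibble(lambda = cv$lambda, cvm = cv$cvm),
    fit = fit
  ), class = "mutability_model")
}

#' @export
print.mutability_model <- function(x, ...) {
  cat(sprintf("<mutability_model> %d predictors, lambda = %.3g, alpha = %.2g\n",
              length(x$coefficients), x$lambda, x$alpha))
  cat(sprintf("  training: %s mutated vs %s random sites; deviance ratio %.3f\n",
              format(x$n_mutated, big.mark = ","),
              format(x$n_random, big.mark = ","), x$dev_ratio))
  top <- head(odds_ratios(x), 5)
  cat("  strongest predictors (odds ratio):\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %-28s %.3f\n", top$predictor[i], top$odds_ratio[i]))
  }
  invisible(x)
}

#' Odds ratios of the mutability predictors
#'
#' `OR = e^c` per coefficient; a zeroed-out coefficient gives OR = 1.
#'
#' @param model A `mutability_model`.
#' @return Tibble `predictor, coefficient, odds_ratio`, sorted by
#'   `|log OR|` descending.
#' @export
odds_ratios <- function(model) {
  stopifnot(inherits(model, "mutability_model"))
  tibble(predictor = names(model$coefficients),
         coefficient = unname(model$coefficients),
         odds_ratio = exp(unname(model$coefficients))) |>
    arrange(dplyr::desc(abs(.data$coefficient)))
}

#' @export
tidy.mutability_model <- function(x, ...) odds_ratios(x)

#' @export
glance.mutability_model <- function(x, ...) {
  tibble(lambda = x$lambda, alpha = x$alpha,
         n_predictors = length(x$coefficients),
         n_mutated = x$n_mutated, n_random = x$n_random,
         dev_ratio = x$dev_ratio, null_deviance = x$null_deviance)
}

#' Predict site mutability
#'
#' Per-site probability of carrying a mutation under the fitted model;
#' meaningful relative to the training prevalence. Sites whose features
#' cannot be computed (masked windows) get `NA`.
#'
#' @param model A `mutability_model`.
#' @param newdata Feature tibble (as from [site_features()]) or an
#'   already-expanded numeric matrix with the model's schema.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_mutability <- function(model, newdata) {
  stopifnot(inherits(model, "mutability_model"))
  x <- if (is.matrix(newdata)) {
    newdata[, model$schema, drop = FALSE]
  } else {
    expand_features(as_tibble(newdata), schema = model$schema)
  }
  p <- as.numeric(predict(model$fit, newx = x, type = "response"))
  if (!is.matrix(newdata)) {
    flag <- if ("complexity" %in% names(newdata)) is.na(newdata$complexity) else FALSE
    p[flag] <- NA_real_
  }
  p
}

#' Bin-wise mutation-rate calibration of predicted mutability
#'
#' Combines predicted mutabilities into fixed-width bins (default
#' `[0, 0.12)` in steps of 0.015, i.e. 8 bins), computes the mutation rate
#' of each bin as `SNP_b / (B * G)` and regresses rate on the bin midpoint
#' (Pearson). Empty bins are excluded from the regression with a note.
#'
#' @param predictions Predicted mutability per site.
#' @param is_mutation Logical, whether each site carries a mutation.
#' @param bin_width Bin width (default 0.015).
#' @param range Mutability range covered (default `c(0, 0.12)`).
#' @param G Mean generations entering the rate denominator.
#' @return A `mutability_bins` list: `bins` tibble (`bin_lo, bin_hi, mid,
#'   SNP_b, B, rate`) and `regression` one-row tibble (`slope, intercept,
#'   r, r_squared, p_value, n_bins`).
#' @export
bin_rates <- function(predictions, is_mutation, bin_width = 0.015,
                      range = c(0, 0.12), G = 40.3) {
  stopifnot(length(predictions) == length(is_mutation))
  keep <- !is.na(predictions) & predictions >= range[1] & predictions < range[2]
  p <- predictions[keep]; m <- as.logical(is_mutation)[keep]
  breaks <- seq(range[1], range[2], by = bin_width)
  idx <- findInterval(p, breaks, rightmost.closed = FALSE)
  bins <- tibble(
    bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
    mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
    SNP_b = vapply(seq_len(length(breaks) - 1L),
                   function(b) sum(m[idx == b]), numeric(1)),
    B = vapply(seq_len(length(breaks) - 1L),
               function(b) sum(idx == b), numeric(1))
  ) |>
    mutate(rate = if_else(.data$B > 0, .data$SNP_b / (.data$B * G), NA_real_))
  usable <- bins |> filter(.data$B > 0)
  reg <- if (nrow(usable) >= 3) {
    fit <- lm(rate ~ mid, data = usable)
    r <- suppressWarnings(cor(usable$mid, usable$rate))
    tibble(slope = coef(fit)[["mid"]], intercept = coef(fit)[["(Intercept)"]],
           r = r, r_squared = r^2,
           p_value = summary(fit)$coefficients["mid", 4],
           n_bins = nrow(usable))
  } else {
    tibble(slope = NA_real_, intercept = NA_real_, r = NA_real_,
           r_squared = NA_real_, p_value = NA_real_, n_bins = nrow(usable))
  }
  structure(list(bins = bins, regression = reg), class = "mutability_bins")
}

#' @export
print.mutability_bins <- function(x, ...) {
  cat(sprintf("<mutability_bins> %d bins; rate-vs-mutability r = %.3f (R^2 = %.3f)\n",
              nrow(x$bins), x$regression$r, x$regression$r_squared))
  print(x$bins)
  invisible(x)
}

#' @export
tidy.mutability_bins <- function(x, ...) x$bins

#' @export
glance.mutability_bins <- function(x, ...) x$regression
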