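#' Diagnostic gates
#'
#' `gate_eoe()` implements the primary diagnosis gate of the published
#' algorithm: an EoE diagnosis is made when the composite probability
#' p(EoE) exceeds 25 (strictly; p(EoE) is on the 0-100 scale).
#' `apply_ighe_loop()` implements the published secondary loop for elevated
#' esophageal IgE-pathway activity: elevated when the IGHE score strictly
#' exceeds 37.5. Both are pure threshold functions; loops annotate samples
#' independently and in any order.
#'
#' @param p_eoe p(EoE) values in `[0, 100]`.
#' @return Logical vector.
#' @export
gate_eoe <- function(p_eoe) {
  if (any(!is.finite(p_eoe)) || any(p_eoe < 0 | p_eoe > 100))
    stop("p(EoE) must lie in [0, 100]")
  p_eoe > 25
}

#' @rdname gate_eoe
#' @param ighe_score Finite IGHE scores.
#' @export
apply_ighe_loop <- function(ighe_score) {
  if (any(is.na(ighe_score))) stop("IGHE scores must be finite")
  ighe_score > 37.5
}

#' Default disease-probability model (pluggable stand-in)
#'
#' A regularized multinomial linear model (ridge, fixed lambda) on per-gene
#' standardized log2 expression, returning probability triples over
#' `{Control, EoE, GERD}` that sum to 100 by construction (classes absent
#' from training get probability 0). This is deliberately a pluggable
#' default for the primary gate — it does not reproduce the coefficients of
#' any published classifier. The fitted object is serializable with
#' `saveRDS()` and deterministic given its inputs.
#'
#' @param norm A `normalized_matrix` of training samples.
#' @param labels Training class per sample, in `{Control, EoE, GERD}`; at
#'   least two classes must be present.
#' @param lambda Ridge penalty, default 0.01.
#' @return An object of class `eoe_prob_model`.
#' @export
fit_probability_model <- function(norm, labels, lambda = 0.01) {
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("Control", "EoE", "GERD")))
  if (length(unique(labels)) < 2)
    stop("probability model needs >= 2 classes in training labels")
  expr <- log_expression(norm)
  mu <- rowMeans(expr)
  sdv <- apply(expr, 1, stats::sd)
  sdv[sdv == 0] <- 1
  x <- t((expr - mu) / sdv)
  fam <- if (length(unique(labels)) == 2) "binomial" else "multinomial"
  fit <- glmnet::glmnet(x, factor(labels), family = fam, alpha = 0,
                        lambda = lambda, standardize = FALSE)
  structure(list(fit = fit, family = fam, classes = sort(unique(labels)),
                 genes = rownames(expr), mu = mu, sd = sdv,
                 lambda = lambda),
            class = "eoe_prob_model")
}

#' @rdname fit_probability_model
#' @param model A fitted `eoe_prob_model`.
#' @param newdata A `normalized_matrix` of samples to score.
#' @return `data.frame` with columns `sample_id`, `p_Control`, `p_EoE`,
#'   `p_GERD`, each in `[0, 100]`, summing to 100 per sample.
#' @export
predict_probabilities <- function(model, newdata) {
  expr <- log_expression(newdata)[model$genes, , drop = FALSE]
  x <- t((expr - model$mu) / model$sd)
  pr <- stats::predict(model$fit, newx = x, type = "response")
  probs <- matrix(0, nrow(x), 3,
                  dimnames = list(rownames(x), c("Control", "EoE", "GERD")))
  if (model$family == "binomial") {
    # glmnet binomial reports P(second level)
    probs[, model$classes[2]] <- pr[, 1]
    probs[, model$classes[1]] <- 1 - pr[, 1]
  } else {
    probs[, colnames(pr[, , 1])] <- pr[, , 1]
  }
  data.frame(sample_id = rownames(x),
             p_Control = 100 * probs[, "Control"],
             p_EoE = 100 * probs[, "EoE"],
             p_GERD = 100 * probs[, "GERD"],
             row.names = NULL, stringsAsFactors = FALSE)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full diagnostic pipeline
#'
#' Executes the analysis end to end: control-based normalization, the
#' optional primary EoE probability gate, three-group differential
#' expression, FI transcript weights, the composite standardized FI-score
#' with its ROC-derived (or fixed) cutoff, and per-sample loop decisions.
#' The FI loop runs only on EoE samples (gated or labeled); controls never
#' receive FI calls. Errors carry the name of the failing stage.
#'
#' @param raw A [raw_count_set()].
#' @param metadata A `clinical_table` aligned with the lanes by `sample_id`.
#' @param config Nested list of stage options:
#'   `normalization$background` (`"mean"`/`"mean2sd"`/`"none"`),
#'   `gate$enabled` (default `FALSE`: the labeled EoE samples are scored),
#'   `gate$p_eoe` (default 25), `ighe$cutoff` (default 37.5; applied when
#'   metadata has an `ighe_score` column), `score$alpha` (default 0.05),
#'   `score$cutoff_policy` (`"youden"`, `"max_specificity"`, or a number for
#'   a fixed cutoff).
#' @return A list of class `fi_pipeline_result`: `normalized`, `de`,
#'   `fi` (an `fi_score_result`), `probabilities` (when gated), and
#'   `decisions` — one row per sample with group, gate results, scores and
#'   calls.
#' @export
run_pipeline <- function(raw, metadata, config = list()) {
  cfg <- utils::modifyList(
    list(normalization = list(background = "mean"),
         gate = list(enabled = FALSE, p_eoe = 25),
         ighe = list(cutoff = 37.5),
         score = list(alpha = 0.05, cutoff_policy = "youden")),
    config)
  metadata <- validate_clinical_table(as.data.frame(metadata))
  ids <- colnames(raw$counts)
  if (!setequal(ids, metadata$sample_id))
    stop("metadata sample ids do not match count lanes")
  metadata <- metadata[match(ids, metadata$sample_id), ]
  group <- factor(metadata$group, levels = GROUP_LEVELS)

  norm <- with_stage("normalization",
                     normalize_lanes(raw, background = cfg$normalization$background))
  kept <- colnames(norm$values)
  group <- group[match(kept, ids)]
  metadata <- metadata[match(kept, metadata$sample_id), ]

  probs <- NULL
  eoe_gate <- group %in% c("EoE_no_FI", "EoE_FI")
  if (isTRUE(cfg$gate$enabled)) {
    probs <- with_stage("probability_gate", {
      train_lab <- ifelse(group == "Control", "Control", "EoE")
      model <- fit_probability_model(norm, train_lab)
      predict_probabilities(model, norm)
    })
    eoe_gate <- probs$p_EoE > cfg$gate$p_eoe
  }

  de <- with_stage("differential_expression", run_de(norm, group))
  fi <- with_stage("fi_score",
                   fi_signature(norm, group, de = de,
                                alpha = cfg$score$alpha,
                                cutoff_policy = cfg$score$cutoff_policy))

  ighe_flag <- if ("ighe_score" %in% names(metadata))
    ifelse(is.na(metadata$ighe_score), NA,
           metadata$ighe_score > cfg$ighe$cutoff)
  else rep(NA, length(kept))

  fi_score <- fi_call <- rep(NA, length(kept))
  idx <- match(names(fi$standardized), kept)
  fi_score[idx] <- fi$standardized
  fi_call[idx] <- fi$calls
  decisions <- data.frame(
    sample_id = kept, group = as.character(group),
    p_eoe = if (is.null(probs)) NA_real_ else probs$p_EoE,
    eoe_gate = eoe_gate, ighe_elevated = ighe_flag,
    fi_score = as.numeric(fi_score), fi_call = as.logical(fi_call),
    stringsAsFactors = FALSE)

  structure(list(normalized = norm, de = de, fi = fi,
                 probabilities = probs, decisions = decisions,
                 config = cfg),
            class = "fi_pipeline_result")
}
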