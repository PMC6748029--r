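#' Classification rule configuration
#'
#' Thresholds and policies for the IL-1b/IL-10 subgroup rules. The printed
#' criteria are: high when the ratio exceeds the control mean + 2 SD under at
#' least one culture condition and/or exceeds + 1 SD under more than two
#' conditions (read literally as >= 3 of the four, configurable); low when
#' the ratio falls below the control mean - 1 SD under at least one
#' condition; normal when all conditions sit inside the +/- 1 SD band or
#' exactly one condition sits in the (+1 SD, +2 SD] band. Patterns the
#' printed rules do not cover (exactly two conditions in the +1..+2 SD band)
#' are resolved by `gap_policy`; a simultaneous high and low firing by
#' `conflict_policy`.
#'
#' @param conditions_used conditions entering classification (`NULL` = all
#'   conditions present).
#' @param high_2sd_min_conditions,high_1sd_min_conditions,low_1sd_min_conditions
#'   minimum numbers of conditions required to fire each criterion.
#' @param conflict_policy `"strict"` (high and low both firing gives
#'   `ambiguous`) or `"max_abs_z"` (the tail with the larger absolute
#'   z-score wins).
#' @param gap_policy currently only `"assign_normal_flagged"`.
#' @param min_control minimum controls with valid ratios per condition.
#' @return an object of class `rule_config`.
#' @export
rule_config <- function(conditions_used = NULL,
                        high_2sd_min_conditions = 1L,
                        high_1sd_min_conditions = 3L,
                        low_1sd_min_conditions = 1L,
                        conflict_policy = c("strict", "max_abs_z"),
                        gap_policy = "assign_normal_flagged",
                        min_control = 5L) {
  structure(list(conditions_used = conditions_used,
                 high_2sd_min_conditions = high_2sd_min_conditions,
                 high_1sd_min_conditions = high_1sd_min_conditions,
                 low_1sd_min_conditions = low_1sd_min_conditions,
                 conflict_policy = match.arg(conflict_policy),
                 gap_policy = gap_policy,
                 min_control = as.integer(min_control)),
            class = "rule_config")
}

#' Compute per-subject, per-condition IL-1b/IL-10 ratios
#'
#' Cells where IL-10 is zero (or left-censored at the assay floor) are
#' flagged invalid instead of producing infinities; an IL-1b of zero gives a
#' valid ratio of 0.
#'
#' @param cytokine_table long table with columns `subject_id`, `condition`,
#'   `cytokine`, `pg_ml` (and optionally `censored`).
#' @param il1b,il10 cytokine names used as numerator / denominator.
#' @return data frame of class `ratio_table` with columns `subject_id`,
#'   `condition`, `ratio`, `valid`.
#' @export
compute_ratio_table <- function(cytokine_table, il1b = "IL-1b",
                                il10 = "IL-10") {
  assert_columns(cytokine_table,
                 c("subject_id", "condition", "cytokine", "pg_ml"))
  for (k in c(il1b, il10)) {
    if (!k %in% cytokine_table$cytokine) {
      stop_serumir("cytokine '%s' missing from cytokine table", k,
                   class = "serumir_parse_error")
    }
  }
  cens <- cytokine_table$censored %||% rep(FALSE, nrow(cytokine_table))
  key <- paste(cytokine_table$subject_id, cytokine_table$condition, sep = "\r")
  i1 <- cytokine_table$cytokine == il1b
  i10 <- cytokine_table$cytokine == il10
  num <- stats::setNames(cytokine_table$pg_ml[i1], key[i1])
  den <- stats::setNames(cytokine_table$pg_ml[i10], key[i10])
  den_cens <- stats::setNames(cens[i10], key[i10])
  keys <- intersect(names(num), names(den))
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  valid <- is.finite(den[keys]) & den[keys] > 0 & !den_cens[keys] &
    is.finite(num[keys]) & num[keys] >= 0
  out <- data.frame(subject_id = parts[, 1L], condition = parts[, 2L],
                    ratio = ifelse(valid, num[keys] / den[keys], NA_real_),
                    valid = unname(valid), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' Control reference statistics per culture condition
#'
#' Sample mean and SD (n - 1 denominator) of control-subject ratios over
#' valid cells, per condition.
#'
#' @param ratio_table output of [compute_ratio_table()].
#' @param control_ids subject ids of the control group.
#' @param min_control minimum valid controls required per condition.
#' @return data frame of class `control_reference` with columns `condition`,
#'   `mean`, `sd`, `n`.
#' @export
control_reference <- function(ratio_table, control_ids, min_control = 5L) {
  rt <- ratio_table[ratio_table$subject_id %in% control_ids &
                      ratio_table$valid, , drop = FALSE]
  conds <- unique(ratio_table$condition)
  out <- do.call(rbind, lapply(conds, function(cc) {
    x <- rt$ratio[rt$condition == cc]
    data.frame(condition = cc, mean = mean(x), sd = stats::sd(x),
               n = length(x), stringsAsFactors = FALSE)
  }))
  bad <- out$n < min_control
  if (any(bad)) {
    stop_serumir("degenerate reference: fewer than %d valid controls in %s",
                 min_control, paste(out$condition[bad], collapse = ", "),
                 class = "serumir_reference_error")
  }
  if (any(!is.finite(out$sd) | out$sd <= 0)) {
    stop_serumir("degenerate reference: zero control SD in %s",
                 paste(out$condition[!is.finite(out$sd) | out$sd <= 0],
                       collapse = ", "),
                 class = "serumir_reference_error")
  }
  class(out) <- c("control_reference", "data.frame")
  out
}

# Core rule engine on a ratio vector aligned with mean/sd vectors.
# Returns just the label; classify_subject() wraps it with bookkeeping.
categorize_ratios <- function(ratios, mu, sigma, rules) {
  ok <- is.finite(ratios)
  ratios <- ratios[ok]; mu <- mu[ok]; sigma <- sigma[ok]
  n_above2 <- sum(ratios > mu + 2 * sigma)
  n_above1 <- sum(ratios > mu + sigma)          # includes > 2 SD
  n_below1 <- sum(ratios < mu - sigma)
  band <- n_above1 - n_above2                   # strictly inside (+1, +2]
  high <- n_above2 >= rules$high_2sd_min_conditions ||
    n_above1 >= rules$high_1sd_min_conditions
  low <- n_below1 >= rules$low_1sd_min_conditions
  if (high && low) {
    if (rules$conflict_policy == "strict") return("ambiguous")
    z <- (ratios - mu) / sigma
    return(if (max(z) >= abs(min(z))) "high" else "low")
  }
  if (high) return("high")
  if (low) return("low")
  "normal"
}

#' Classify one subject against the control reference
#'
#' Applies the high/normal/low rules of [rule_config()] to a subject's
#' per-condition ratios. Invalid (censored-denominator) cells are excluded
#' from the condition counts. Returns the label together with the fired
#' rules and flags for rule gaps and conflicts.
#'
#' @param subject_ratios named numeric vector of ratios (names = conditions);
#'   `NA` marks invalid cells.
#' @param reference a [control_reference()] table.
#' @param rules a [rule_config()].
#' @return list of class `subgroup_label` with elements `value`
#'   (high/normal/low/ambiguous), `fired_rules` (data frame `condition`,
#'   `criterion`), `rule_gap`, `conflict`, `n_valid`.
#' @export
classify_subject <- function(subject_ratios, reference,
                             rules = rule_config()) {
  conds <- rules$conditions_used %||% reference$condition
  conds <- intersect(conds, names(subject_ratios))
  r <- subject_ratios[conds]
  ref <- reference[match(conds, reference$condition), , drop = FALSE]
  ok <- is.finite(r)
  if (!any(ok)) {
    stop_serumir("subject has no valid condition to classify",
                 class = "serumir_unclassifiable_error")
  }
  r <- r[ok]; mu <- ref$mean[ok]; sigma <- ref$sd[ok]
  cond_ok <- conds[ok]
  above2 <- r > mu + 2 * sigma
  above1 <- r > mu + sigma
  below1 <- r < mu - sigma
  band <- above1 & !above2
  fired <- rbind(
    if (any(above2)) data.frame(condition = cond_ok[above2],
                                criterion = "gt_2sd"),
    if (any(band)) data.frame(condition = cond_ok[band],
                              criterion = "gt_1sd"),
    if (any(below1)) data.frame(condition = cond_ok[below1],
                                criterion = "lt_minus_1sd"))
  if (is.null(fired)) {
    fired <- data.frame(condition = character(), criterion = character())
  }
  high <- sum(above2) >= rules$high_2sd_min_conditions ||
    sum(above1) >= rules$high_1sd_min_conditions
  low <- sum(below1) >= rules$low_1sd_min_conditions
  conflict <- high && low
  gap <- FALSE
  if (conflict) {
    if (rules$conflict_policy == "strict") {
      value <- "ambiguous"
    } else {
      z <- (r - mu) / sigma
      value <- if (max(z) >= abs(min(z))) "high" else "low"
    }
  } else if (high) {
    value <- "high"
  } else if (low) {
    value <- "low"
  } else {
    # neither tail fired; the printed normal rule covers band counts 0 or 1
    value <- "normal"
    gap <- sum(band) >= 2L
  }
  structure(list(value = value, fired_rules = fired, rule_gap = gap,
                 conflict = conflict, n_valid = sum(ok)),
            class = "subgroup_label")
}

#' @export
print.subgroup_label <- function(x, ...) {
  cat("subgroup:", x$value,
      if (x$rule_gap) "(rule gap)" else "",
      if (x$conflict) "(high/low conflict)" else "", "\n")
  invisible(x)
}

#' Reconcile subgroup labels across timepoints
#'
#' Identical labels keep that label; a mix of normal and low resolves to low
#' (the handling reported for the one discordant subject in the source
#' cohort), symmetrically normal + high resolves to high; any mix involving
#' both high and low, or an ambiguous component, is `ambiguous`.
#'
#' @param labels character vector of per-timepoint labels (or a list of
#'   `subgroup_label` objects).
#' @return a single label string.
#' @export
reconcile_timepoints <- function(labels) {
  if (is.list(labels)) {
    labels <- vapply(labels, function(l) {
      if (inherits(l, "subgroup_label")) l$value else as.character(l)
    }, character(1))
  }
  if (!length(labels)) {
    stop_serumir("no labels to reconcile", class = "serumir_config_error")
  }
  u <- unique(labels)
  if (length(u) == 1L) return(u)
  if ("ambiguous" %in% u) return("ambiguous")
  if (all(c("high", "low") %in% u)) return("ambiguous")
  if ("high" %in% u) return("high")
  if ("low" %in% u) return("low")
  "normal"
}

#' Classify every ASD subject in a cohort
#'
#' Computes the ratio table, derives the control reference from the cohort's
#' control subjects, classifies each ASD subject-timepoint, and reconciles
#' labels across timepoints. Every fired rule, gap and conflict is recorded
#' in an audit log with one record per subject-timepoint.
#'
#' @param dataset a `cohort_dataset` (or any list with `subjects` and
#'   `cytokine_table`).
#' @param rules a [rule_config()].
#' @return list with `labels` (data frame `subject_id`, `label`, `rule_gap`,
#'   `conflict`, `fired_rules`), `audit` (list of per-subject-timepoint
#'   records) and `reference`.
#' @export
classify_cohort <- function(dataset, rules = rule_config()) {
  cyt <- dataset$cytokine_table
  has_tp <- "timepoint" %in% names(cyt)
  rt <- compute_ratio_table(cyt)
  controls <- dataset$subjects$subject_id[
    tolower(dataset$subjects$diagnosis) == "control"]
  ref <- control_reference(rt, controls, min_control = rules$min_control)
  asd <- dataset$subjects[tolower(dataset$subjects$diagnosis) != "control", ,
                          drop = FALSE]
  audit <- list()
  per_subject <- split(asd, asd$subject_id)
  rows <- lapply(per_subject, function(sd) {
    sid <- sd$subject_id[1L]
    tps <- sort(unique(sd$timepoint))
    tl <- lapply(tps, function(tp) {
      sub <- if (has_tp) {
        compute_ratio_table(cyt[cyt$subject_id == sid &
                                  cyt$timepoint == tp, , drop = FALSE])
      } else {
        rt[rt$subject_id == sid, , drop = FALSE]
      }
      ratios <- stats::setNames(sub$ratio, sub$condition)
      lab <- classify_subject(ratios, ref, rules)
      audit[[length(audit) + 1L]] <<- list(
        subject_id = sid, timepoint = tp, label = lab$value,
        fired_rules = lab$fired_rules, rule_gap = lab$rule_gap,
        conflict = lab$conflict, n_valid = lab$n_valid)
      lab
    })
    final <- reconcile_timepoints(tl)
    data.frame(
      subject_id = sid, label = final,
      rule_gap = any(vapply(tl, `[[`, logical(1), "rule_gap")),
      conflict = any(vapply(tl, `[[`, logical(1), "conflict")),
      fired_rules = paste(unique(unlist(lapply(tl, function(l) {
        paste(l$fired_rules$condition, l$fired_rules$criterion, sep = ":")
      }))), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  labels <- do.call(rbind, rows)
  labels <- labels[match(unique(asd$subject_id), labels$subject_id), ,
                   drop = FALSE]
  rownames(labels) <- NULL
  list(labels = labels, audit = audit, reference = ref)
}
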