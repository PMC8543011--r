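#' Configuration for the synthetic flow-cytometry event generator
#'
#' Describes a mixture-of-subpopulations model for an 8-hour TIL/tumor-cell
#' co-culture readout. Each live event belongs to one functional class (a
#' Boolean combination of CD137, TNF, IFN-gamma and optionally CD107a); channel
#' intensities are drawn from a two-component (negative/positive)
#' location-scale model on an arcsinh-like transformed scale. CD137-positive
#' events are split between surface-positive and intracellular-positive
#' occupancy states; protein-transport inhibitors shift that occupancy
#' (relocation, not loss), which is how brefeldin A and monensin act on CD137.
#'
#' @param n_events Events generated per condition.
#' @param subset_mix Named fractions for `CD8` and `CD4` (must sum to 1).
#' @param class_fractions Named list with one named numeric vector per subset
#'   mapping functional-class labels (see [combo_labels()]) to fractions
#'   summing to 1. Defaults place 30% (CD8) / 25% (CD4) of events in reactive
#'   classes.
#' @param channel_params Named list per activation channel with `neg` and
#'   `pos` components, each `c(mean, sd)` on the transformed scale. The
#'   positive location must exceed the negative location.
#' @param background_rate Spurious per-marker positive rate among
#'   all-negative-class events (applied in every condition, so control
#'   conditions carry it too).
#' @param cd137_occupancy Baseline probabilities `c(surface, intracellular)`
#'   that a CD137-positive event displays each form (before conditioning on at
#'   least one form being positive).
#' @param inhibitor_effects Named list per inhibitor condition
#'   (`none`, `BFA`, `MN`, `BFA+MN`) of multiplicative shifts
#'   `c(surface, intracellular)` applied to the occupancy probabilities.
#' @param viability_rate Fraction of live events; dead events are excluded by
#'   the viability gate downstream.
#' @param seed Integer seed; identical seed and config give bit-identical
#'   output.
#' @return An object of class `flow_sim_config`.
#' @export
flow_sim_config <- function(n_events = 50000,
                            subset_mix = c(CD8 = 0.6, CD4 = 0.4),
                            class_fractions = NULL,
                            channel_params = NULL,
                            background_rate = 0.0005,
                            cd137_occupancy = c(surface = 0.85, intracellular = 0.70),
                            inhibitor_effects = NULL,
                            viability_rate = 0.97,
                            seed = 1L) {
  if (n_events < 1) stop_config("n_events", "must be >= 1")
  if (abs(sum(subset_mix) - 1) > 1e-9 || any(subset_mix < 0))
    stop_config("subset_mix", "fractions must be non-negative and sum to 1")
  if (!all(c("CD8", "CD4") %in% names(subset_mix)))
    stop_config("subset_mix", "must name CD8 and CD4")
  if (is.null(class_fractions))
    class_fractions <- list(CD8 = default_class_fractions(0.30),
                            CD4 = default_class_fractions(0.25))
  labels <- combo_labels(FLOW_MARKERS)
  for (ss in c("CD8", "CD4")) {
    cf <- class_fractions[[ss]]
    if (is.null(cf)) stop_config("class_fractions", paste("missing subset", ss))
    if (!all(names(cf) %in% labels))
      stop_config("class_fractions",
                  paste("unknown class label(s):",
                        paste(setdiff(names(cf), labels), collapse = ", ")))
    if (abs(sum(cf) - 1) > 1e-9 || any(cf < 0))
      stop_config("class_fractions", paste(ss, "fractions must sum to 1"))
  }
  if (is.null(channel_params)) channel_params <- default_channel_params()
  for (ch in ACTIVATION_CHANNELS) {
    cp <- channel_params[[ch]]
    if (is.null(cp)) stop_config("channel_params", paste("missing channel", ch))
    if (cp$pos[1] <= cp$neg[1])
      stop_config("channel_params",
                  paste0(ch, ": positive location must exceed negative location"))
  }
  if (background_rate < 0 || background_rate > 1)
    stop_config("background_rate", "must lie in [0, 1]")
  if (viability_rate < 0 || viability_rate > 1)
    stop_config("viability_rate", "must lie in [0, 1]")
  if (any(cd137_occupancy <= 0) || any(cd137_occupancy > 1))
    stop_config("cd137_occupancy", "probabilities must lie in (0, 1]")
  if (is.null(inhibitor_effects)) inhibitor_effects <- default_inhibitor_effects()
  structure(list(n_events = as.integer(n_events), subset_mix = subset_mix,
                 class_fractions = class_fractions,
                 channel_params = channel_params,
                 background_rate = background_rate,
                 cd137_occupancy = cd137_occupancy,
                 inhibitor_effects = inhibitor_effects,
                 viability_rate = viability_rate, seed = as.integer(seed)),
            class = "flow_sim_config")
}

## 30%-reactive default: reactive mass spread over the CD137/TNF/IFNg combos,
## CD107a mostly riding along with IFNg (its marginal contribution is small)
default_class_fractions <- function(reactive_total) {
  labels <- combo_labels(FLOW_MARKERS)
  f <- setNames(numeric(length(labels)), labels)
  w <- c("CD137+TNF+IFNg+CD107a+" = 0.18, "CD137+TNF+IFNg+CD107a-" = 0.14,
         "CD137+TNF+IFNg-CD107a-" = 0.13, "CD137+TNF-IFNg+CD107a-" = 0.08,
         "CD137+TNF-IFNg-CD107a-" = 0.24, "CD137-TNF+IFNg+CD107a-" = 0.07,
         "CD137-TNF+IFNg-CD107a-" = 0.09, "CD137-TNF-IFNg+CD107a-" = 0.04,
         "CD137-TNF-IFNg+CD107a+" = 0.02, "CD137-TNF-IFNg-CD107a+" = 0.01)
  f[names(w)] <- w / sum(w) * reactive_total
  f["CD137-TNF-IFNg-CD107a-"] <- 1 - reactive_total
  f
}

default_channel_params <- function() {
  act <- list(neg = c(1.0, 0.35), pos = c(4.0, 0.40))
  c(setNames(rep(list(act), length(ACTIVATION_CHANNELS)), ACTIVATION_CHANNELS),
    list(CD4 = list(neg = c(0.8, 0.3), pos = c(3.5, 0.4)),
         CD8 = list(neg = c(0.8, 0.3), pos = c(3.5, 0.4)),
         viability = list(neg = c(0.5, 0.3), pos = c(3.0, 0.4))))
}

## Occupancy multipliers chosen so that transport inhibition depletes the
## surface form and enriches the intracellular form while total CD137 is
## conserved by construction (every CD137+ event keeps at least one form).
default_inhibitor_effects <- function() {
  list(none      = c(surface = 1.00, intracellular = 1.00),
       BFA       = c(surface = 0.24, intracellular = 1.35),
       MN        = c(surface = 0.98, intracellular = 1.45),
       `BFA+MN`  = c(surface = 0.21, intracellular = 1.38))
}

#' Generate synthetic flow-cytometry event tables with ground truth
#'
#' Draws one event table per requested condition (autologous co-culture,
#' allogeneic co-culture, TILs alone) crossed with the requested inhibitor
#' variants. Control conditions (allogeneic, alone) draw all non-background
#' events from the all-negative class. Latent class labels are returned only
#' in the truth object.
#'
#' @param config A [flow_sim_config()].
#' @param conditions Conditions to generate, subset of
#'   `c("autologous", "allogeneic", "alone")`.
#' @param inhibitors Inhibitor variants, subset of
#'   `c("none", "BFA", "MN", "BFA+MN")`.
#' @return A list with `events` (named list of `event_table` data frames, one
#'   per condition x inhibitor) and `truth` (a `synthetic_truth` object with
#'   per-event latent labels and the config echo).
#' @examples
#' sim <- generate_flow_events(flow_sim_config(n_events = 500, seed = 7))
#' names(sim$events)
#' @export
generate_flow_events <- function(config,
                                 conditions = c("autologous", "allogeneic", "alone"),
                                 inhibitors = "none") {
  stopifnot(inherits(config, "flow_sim_config"))
  conditions <- match.arg(conditions, c("autologous", "allogeneic", "alone"),
                          several.ok = TRUE)
  bad <- setdiff(inhibitors, names(config$inhibitor_effects))
  if (length(bad)) stop_config("inhibitors", paste("unknown:", paste(bad, collapse = ", ")))
  with_seed(config$seed, {
    events <- list()
    truth_tabs <- list()
    for (inh in inhibitors) {
      for (cond in conditions) {
        key <- if (inh == "none") cond else paste(cond, inh, sep = ".")
        sim <- simulate_condition(config, cond, inh, sample_id = key)
        events[[key]] <- sim$events
        truth_tabs[[key]] <- sim$truth
      }
    }
    truth <- structure(list(labels = do.call(rbind, truth_tabs),
                            config = config, kind = "flow"),
                       class = "synthetic_truth")
    rownames(truth$labels) <- NULL
    list(events = events, truth = truth)
  })
}

simulate_condition <- function(config, condition, inhibitor, sample_id) {
  n <- config$n_events
  labels <- combo_labels(FLOW_MARKERS)
  allneg <- "CD137-TNF-IFNg-CD107a-"
  subset <- sample(names(config$subset_mix), n, TRUE, config$subset_mix)
  cls <- character(n)
  for (ss in unique(subset)) {
    idx <- subset == ss
    if (condition == "autologous") {
      cf <- config$class_fractions[[ss]]
      cls[idx] <- sample(names(cf), sum(idx), TRUE, cf)
    } else {
      cls[idx] <- allneg
    }
  }
  pos <- matrix(FALSE, n, length(FLOW_MARKERS),
                dimnames = list(NULL, FLOW_MARKERS))
  for (lab in unique(cls)) {
    idx <- which(cls == lab)
    pos[idx, ] <- matrix(parse_combo(lab, FLOW_MARKERS), length(idx),
                         length(FLOW_MARKERS), byrow = TRUE)
  }
  ## spurious background positivity among all-negative-class events
  if (config$background_rate > 0) {
    bg_idx <- which(cls == allneg)
    for (m in FLOW_MARKERS)
      pos[bg_idx, m] <- stats::runif(length(bg_idx)) < config$background_rate
  }
  ## CD137 occupancy states under inhibitor shift, conditional on CD137+
  eff <- config$inhibitor_effects[[inhibitor]]
  ps <- min(1, config$cd137_occupancy[["surface"]] * eff[["surface"]])
  pi_ <- min(1, config$cd137_occupancy[["intracellular"]] * eff[["intracellular"]])
  st <- c(both = ps * pi_, surface = ps * (1 - pi_), intracellular = (1 - ps) * pi_)
  if (sum(st) <= 0) st <- c(both = 1, surface = 0, intracellular = 0)
  st <- st / sum(st)
  s_pos <- i_pos <- logical(n)
  cd137_idx <- which(pos[, "CD137"])
  if (length(cd137_idx)) {
    state <- sample(names(st), length(cd137_idx), TRUE, st)
    s_pos[cd137_idx] <- state %in% c("both", "surface")
    i_pos[cd137_idx] <- state %in% c("both", "intracellular")
  }
  live <- stats::runif(n) < config$viability_rate
  draw <- function(channel, positive) {
    cp <- config$channel_params[[channel]]
    mu <- ifelse(positive, cp$pos[1], cp$neg[1])
    sd <- ifelse(positive, cp$pos[2], cp$neg[2])
    stats::rnorm(n, mu, sd)
  }
  tab <- data.frame(
    event_id = seq_len(n),
    sample_id = sample_id,
    condition = condition,
    inhibitor = inhibitor,
    CD137s = draw("CD137s", s_pos),
    CD137i = draw("CD137i", i_pos),
    TNF = draw("TNF", pos[, "TNF"]),
    IFNg = draw("IFNg", pos[, "IFNg"]),
    CD107a = draw("CD107a", pos[, "CD107a"]),
    CD4 = draw("CD4", subset == "CD4"),
    CD8 = draw("CD8", subset == "CD8"),
    viability = draw("viability", live),
    stringsAsFactors = FALSE)
  class(tab) <- c("event_table", "data.frame")
  truth <- data.frame(sample_id = sample_id, condition = condition,
                      inhibitor = inhibitor, event_id = seq_len(n),
                      subset = subset, class = cls, live = live,
                      surface_pos = s_pos, ic_pos = i_pos,
                      stringsAsFactors = FALSE)
  list(events = tab, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> kind=%s, %d records, seed=%d\n",
              x$kind, nrow(x$labels %||% data.frame()), x$config$seed))
  invisible(x)
}
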