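#' Advice message catalog
#'
#' The 23 physician-selectable recommendation messages, grouped into six
#' categories (dietary intake, activity, sleep, shift, nap, mentality).
#' Labels are short working titles for reporting; the category mapping is
#' what the statistics and policy machinery rely on.
#'
#' @return `data.table` with columns `message_id`, `category`, `label`.
#' @export
advice_catalog <- function() {
  data.table(
    message_id = 1:23,
    category = c("dietary", "dietary", "dietary", "activity", "activity",
                 "activity", "sleep", "sleep", "sleep", "sleep", "shift",
                 "nap", "nap", "nap", "nap", "activity", "activity",
                 "activity", "mentality", "sleep", "sleep", "sleep", "nap"),
    label = c(
      "no alcohol before sleep", "no caffeine 3h before lights-out",
      "no midnight snacks", "no smartphone in bedroom",
      "bathe earlier than usual", "no exercise 3h before lights-out",
      "darken the bedroom", "leave bedroom if not asleep in 15 min",
      "wake time per work shift", "don't force sleep",
      "request clockwise shift rotation", "90-min nap before night shift",
      "15-20-min nap during work breaks", "nap earlier after late-night shift",
      "set up a nap environment", "relaxation habit before sleep",
      "guided breathing program", "regular moderate exercise",
      "approach things positively", "continue current sleep habits",
      "make enough time for sleep", "fixed wake time on work and rest days",
      "don't nap too long"))
}

#' Construct a physician policy rule
#'
#' A rule fires a message when a windowed feature crosses a threshold,
#' with logistic softness and a floor noise probability; physicians'
#' actual reasoning is unknown, so rules are explicit stand-ins used by
#' the simulator.
#'
#' @param message_id message in 1..23.
#' @param feature name of a window-aggregated feature column (e.g.
#'   `"brightness_sleep_mean"`); `NA` for pure-noise or fallback rules.
#' @param direction `">"` fires for high values, `"<"` for low values.
#' @param threshold feature value at which the firing probability is half
#'   of `p_max`.
#' @param scale logistic softness (feature units).
#' @param p_max maximum predicate-driven firing probability.
#' @param noise probability of firing regardless of the predicate.
#' @param fallback logical: a fallback rule fires only when no other rule
#'   fired for the event.
#' @return a `policy_rule` list.
#' @export
policy_rule <- function(message_id, feature = NA_character_, direction = ">",
                        threshold = 0, scale = 1, p_max = 0, noise = 0,
                        fallback = FALSE) {
  stopifnot(message_id %in% 1:23, direction %in% c(">", "<"),
            p_max >= 0, p_max <= 1, noise >= 0, noise <= 1, scale > 0)
  structure(list(message_id = as.integer(message_id), feature = feature,
                 direction = direction, threshold = threshold, scale = scale,
                 p_max = p_max, noise = noise, fallback = fallback),
            class = "policy_rule")
}

#' Default physician policy
#'
#' One interpretable driving feature per modelled message, calibrated once
#' so that the marginal selection frequencies of the simulated advice log
#' match the observed study-scale proportions (message 20 in about half of
#' the advice pieces, message 21 in about 0.28, minor modelled messages at
#' negative:positive ratios between 5 and 15), plus low-probability noise
#' rules that populate the rarely-chosen tail of the catalog.
#'
#' @return list of [policy_rule()]s, in firing order.
#' @export
default_policy <- function() {
  c(list(
    policy_rule(7L, "brightness_sleep_mean", ">", 41, 7, 0.85, 0.01),
    policy_rule(4L, "phone_use_min_mean", ">", 63, 10, 0.70, 0.01),
    policy_rule(21L, "sleep_duration_min_mean", "<", 341, 38, 0.85, 0.02),
    policy_rule(12L, "work_p3_h_sd", ">", 3.9, 0.35, 0.50, 0.01),
    policy_rule(14L, "caffeine_amount_sd", ">", 1.86, 0.35, 0.50, 0.01),
    policy_rule(15L, "sleep_satisfy_mean", "<", 2.32, 0.3, 0.65, 0.02),
    policy_rule(20L, "sleep_satisfy_mean", ">", 3.18, 0.22, 0.95, 0.0),
    policy_rule(20L, fallback = TRUE)),
    # sparse tail: rarely selected messages
    lapply(c(1L, 2L, 3L, 5L, 6L, 8L, 9L, 10L, 13L, 16L, 17L, 18L, 19L,
             22L, 23L),
           function(m) policy_rule(m, noise = 0.015)))
}

#' Apply a physician policy to aggregated feature windows
#'
#' Each advice event draws independent Bernoulli fires per rule in order;
#' the selected set keeps the first 5 fired messages (selection sets are
#' 1 to 5 messages) and falls back to the designated fallback message when
#' nothing fires. Responses are drawn from the per-message response model
#' of the first (most salient) selected message.
#'
#' @param windows `data.table` with `participant`, `date` and window
#'   feature columns named `<daily feature>_mean` / `_sd`, one row per
#'   advice date with a complete 4-day window.
#' @param policy list of [policy_rule()]s; must be nonempty.
#' @param response_model named list: `difficult` (length-23 vector of
#'   difficult-to-follow probabilities), `eager` and `none` (scalars,
#'   probabilities of the remaining responses given not difficult).
#' @param seed integer seed.
#' @return `data.table` advice log: `participant`, `date`, `message_ids`
#'   (list column), `response`.
#' @export
apply_policy <- function(windows, policy, response_model = NULL, seed = 1L) {
  if (!length(policy)) stop("empty policy")
  windows <- as.data.table(windows)
  rm <- response_model %||% default_response_model()
  set.seed(child_seed(seed, 17L))
  n <- nrow(windows)
  fired <- vector("list", n)
  for (rule in policy) {
    if (isTRUE(rule$fallback)) next
    p <- rep(rule$noise, n)
    if (!is.na(rule$feature)) {
      if (!rule$feature %in% names(windows))
        stop("policy rule for message ", rule$message_id,
             " references unknown window feature '", rule$feature, "'")
      x <- windows[[rule$feature]]
      sgn <- if (rule$direction == ">") 1 else -1
      pr <- rule$p_max * stats::plogis(sgn * (x - rule$threshold) / rule$scale)
      pr[is.na(pr)] <- 0
      p <- pmin(1, p + pr)
    }
    hit <- stats::runif(n) < p
    for (i in which(hit)) fired[[i]] <- c(fired[[i]], rule$message_id)
  }
  fb <- Filter(function(r) isTRUE(r$fallback), policy)
  for (i in seq_len(n)) {
    if (is.null(fired[[i]])) {
      if (length(fb)) fired[[i]] <- fb[[1L]]$message_id
      else fired[[i]] <- policy[[1L]]$message_id
    }
    fired[[i]] <- unique(fired[[i]])[seq_len(min(5L, length(unique(fired[[i]]))))]
  }
  resp <- vapply(seq_len(n), function(i) {
    focal <- fired[[i]][1L]
    if (stats::runif(1) < rm$difficult[focal]) return("difficult")
    if (stats::runif(1) < rm$eager / (rm$eager + rm$none)) "eager" else "none"
  }, character(1))
  data.table(participant = windows$participant, date = windows$date,
             message_ids = fired, response = resp)
}

#' Default per-message response model
#'
#' Difficult-to-follow probabilities are near zero for the
#' keep-doing-what-you-do message (20), high for habit-change messages
#' (smartphone use, caffeine), and moderate elsewhere; conditional on not
#' finding the advice difficult, participants respond eagerly or not at
#' all in roughly a 55:30 split.
#'
#' @return named list with `difficult` (length 23), `eager`, `none`.
#' @export
default_response_model <- function() {
  difficult <- rep(0.05, 23)
  difficult[20] <- 0.005
  difficult[4] <- 0.20
  difficult[2] <- 0.26
  list(difficult = difficult, eager = 0.55, none = 0.30)
}

#' Selection and response statistics of an advice log
#'
#' Mirrors the study-scale summaries: per-message counts and the
#' proportion of advice pieces containing each message, per-category
#' shares of total message occurrences, and the per-message response
#' distribution over advice pieces containing the message.
#'
#' @param advice advice log with `message_ids` (list or pipe-delimited
#'   string) and `response`.
#' @return list with `n_pieces`, `n_occurrences`, `messages`
#'   (`message_id`, `count`, `prop_pieces`), `categories` (`category`,
#'   `count`, `share`), `responses` (`message_id`, `n`, `n_eager`,
#'   `n_difficult`, `n_none`, `difficult_rate`).
#' @export
advice_statistics <- function(advice) {
  advice <- as.data.table(advice)
  if (is.character(advice$message_ids))
    advice[, message_ids := lapply(strsplit(message_ids, "|", fixed = TRUE),
                                   as.integer)]
  n_pieces <- nrow(advice)
  long <- advice[, .(message_id = unlist(message_ids)),
                 by = .(piece = seq_len(n_pieces),
                        response = advice$response)]
  n_occ <- nrow(long)
  msg <- long[, .(count = .N), by = message_id]
  msg <- msg[data.table(message_id = 1:23), on = "message_id"]
  msg[is.na(count), count := 0L]
  msg[, prop_pieces := count / n_pieces]
  setkey(msg, message_id)

  cat_map <- advice_catalog()[, .(message_id, category)]
  catg <- cat_map[long, on = "message_id"][, .(count = .N), by = category]
  catg[, share := count / n_occ]

  resp <- long[, .(n = .N, n_eager = sum(response == "eager"),
                   n_difficult = sum(response == "difficult"),
                   n_none = sum(response == "none")), by = message_id]
  resp[, difficult_rate := n_difficult / n]
  setkey(resp, message_id)

  list(n_pieces = n_pieces, n_occurrences = n_occ, messages = msg[],
       categories = catg[], responses = resp[])
}
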