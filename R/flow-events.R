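# Truncated-normal draw strictly above 0, centered at `mode`.
rtrunc_pos <- function(n, mode, sd) {
  u <- stats::runif(n, stats::pnorm(0, mean = mode, sd = sd), 1)
  stats::qnorm(u, mean = mode, sd = sd)
}

# Required (channel -> sign/threshold) map along a node's ancestor chain.
chain_requirements <- function(tree, name) {
  req <- list()
  for (g in node_chain(tree, name)) req[[g$channel]] <- g
  req
}

#' Simulate bimodal flow-cytometry events with known population labels
#'
#' Draws `n_events` synthetic log-intensity events over all channels of a
#' gating tree. Each event gets a true class by multinomial draw from the
#' requested population fractions, the remainder being `"other"`. Channel
#' intensities are bimodal: an event required to be positive for a channel
#' draws threshold + z and a negative one threshold - z, with z a
#' truncated normal (mode 2, sd 0.5 by default) strictly above 0 — so
#' every population event satisfies exactly its gate chain under the
#' tree's thresholds. Channels a class does not constrain get a random
#' mode. `"other"` events satisfy the chain of the populations' deepest
#' common ancestor (the percentage denominator) but are rejection-resampled
#' until they match no population, emulating the in-denominator events
#' outside all signature gates.
#'
#' @param n_events number of events.
#' @param fractions named numeric vector, population -> fraction; names
#'   must be populations of `tree`; must sum to <= 1.
#' @param tree a [gating_tree()]; default [default_gating_tree()].
#' @param mode,sd bimodal intensity peak offset from threshold and spread.
#' @param seed integer seed; the draw is fully determined by it.
#' @return list: `events` (numeric matrix events x channels), `truth`
#'   (character vector of true classes).
#' @export
generate_flow_events <- function(n_events, fractions,
                                 tree = default_gating_tree(),
                                 mode = 2, sd = 0.5, seed = 0L) {
  stopifnot(inherits(tree, "gating_tree"), n_events >= 1)
  if (length(fractions)) {
    unknown <- setdiff(names(fractions), tree$populations)
    if (length(unknown))
      stop("unknown population name(s): ", paste(unknown, collapse = ", "))
    if (any(fractions < 0) || sum(fractions) > 1 + 1e-12)
      stop("population fractions must be >= 0 and sum to <= 1, got sum = ",
           sum(fractions))
  }
  withr::with_seed(as.integer(seed), {
    channels <- tree_channels(tree)
    classes <- sample(c(names(fractions), "other"), n_events, replace = TRUE,
                      prob = c(fractions, 1 - sum(fractions)))

    # common ancestor = parent shared by the population leaves (the
    # denominator gate); fall back to the root when populations disagree
    nms <- vapply(tree$nodes, `[[`, character(1), "name")
    parents <- vapply(tree$nodes, function(n) n$parent, character(1))
    pop_parents <- unique(parents[match(tree$populations, nms)])
    denom_node <- if (length(pop_parents) == 1L && !is.na(pop_parents))
      pop_parents else nms[1]

    draw_block <- function(n, req) {
      ev <- matrix(NA_real_, n, length(channels),
                   dimnames = list(NULL, channels))
      for (ch in channels) {
        z <- rtrunc_pos(n, mode, sd)
        if (!is.null(req[[ch]])) {
          thr <- req[[ch]]$threshold
          s <- if (req[[ch]]$sign == "+") rep(1, n) else rep(-1, n)
        } else {
          thr <- 0
          s <- sample(c(-1, 1), n, replace = TRUE)
        }
        ev[, ch] <- thr + s * z
      }
      ev
    }

    events <- matrix(NA_real_, n_events, length(channels),
                     dimnames = list(NULL, channels))
    for (cls in unique(classes)) {
      idx <- which(classes == cls)
      req <- chain_requirements(tree, if (cls == "other") denom_node else cls)
      events[idx, ] <- draw_block(length(idx), req)
    }

    # resample "other" events that accidentally satisfy a population chain
    oth <- which(classes == "other")
    if (length(oth)) {
      req <- chain_requirements(tree, denom_node)
      repeat {
        asn <- evaluate_gates(events[oth, , drop = FALSE], tree,
                              denominator = denom_node)$assignment
        bad <- which(asn != "other")
        if (!length(bad)) break
        events[oth[bad], ] <- draw_block(length(bad), req)
      }
    }
    list(events = events, truth = classes)
  })
}
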