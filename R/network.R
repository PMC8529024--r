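#' Build a randomized, frozen antennal lobe network
#'
#' Realizes the circuit: `n_glomeruli` glomeruli each holding
#' `n_PN_per_glom` excitatory projection neurons (PNs) and `n_LN_per_glom`
#' inhibitory local neurons (LNs). Within a glomerulus every ordered cell
#' pair is connected independently with its class probability (PN->PN,
#' PN->LN, LN->PN, LN->LN); across glomeruli only LN->PN synapses occur.
#' Autapses are excluded. Each PN additionally receives a fixed SK current
#' strength: either drawn from Normal(`SK_mu`, `SK_sigma`) and clamped at 0
#' (`sk = "gaussian"`, the standard network), or set to `SK_mu` for every PN
#' (`sk = "fixed"`, the variant used for conductance sweeps of the SK
#' current). In both cases the stored strengths are multiplied by
#' `params$scale_SK`.
#'
#' The construction is a pure function of `(params, seed)`: identical
#' arguments give byte-identical networks.
#'
#' @param params an [al_params()] object.
#' @param seed non-negative integer construction seed.
#' @param sk `"gaussian"` for per-PN Gaussian strengths, `"fixed"` for
#'   identical strengths `SK_mu * scale_SK` across PNs.
#' @return An object of class `al_network` with components
#'   \describe{
#'     \item{neurons}{data.frame with `id`, `class` ("PN"/"LN"),
#'       `glomerulus` (1-based), `sk_strength` (0 for LNs).}
#'     \item{edges}{data.frame with `pre`, `post` neuron ids and
#'       `syn_class` in `PN_PN`, `PN_LN`, `LN_PN`, `LN_LN`.}
#'     \item{params, seed, sk_mode}{the inputs, frozen.}
#'   }
#' @examples
#' net <- al_network(seed = 1)
#' table(net$neurons$class)
#' @export
al_network <- function(params = al_params(), seed = 1L,
                       sk = c("gaussian", "fixed")) {
  stopifnot(inherits(params, "al_params"))
  sk <- match.arg(sk)
  if (!is.numeric(seed) || length(seed) != 1L || seed < 0 ||
      seed != round(seed)) {
    stop("seed must be a single non-negative integer")
  }
  seed <- as.integer(seed)

  ng <- params$n_glomeruli
  npn <- params$n_PN_per_glom
  nln <- params$n_LN_per_glom
  n_pn <- ng * npn
  n_ln <- ng * nln
  # PNs first (glomerulus-major), then LNs: ids are stable across draws
  neurons <- data.frame(
    id = seq_len(n_pn + n_ln),
    class = rep(c("PN", "LN"), c(n_pn, n_ln)),
    glomerulus = c(rep(seq_len(ng), each = npn), rep(seq_len(ng), each = nln)),
    stringsAsFactors = FALSE
  )
  pn_ids <- split(neurons$id[neurons$class == "PN"],
                  neurons$glomerulus[neurons$class == "PN"])
  ln_ids <- split(neurons$id[neurons$class == "LN"],
                  neurons$glomerulus[neurons$class == "LN"])

  ordered_pairs <- function(pre, post, no_autapse) {
    g <- expand.grid(pre = pre, post = post, KEEP.OUT.ATTRS = FALSE)
    if (no_autapse) g <- g[g$pre != g$post, , drop = FALSE]
    g
  }

  edges <- local({
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
    draw <- function(pairs, p, cls) {
      if (nrow(pairs) == 0L || p == 0) {
        return(data.frame(pre = integer(), post = integer(),
                          syn_class = character(), stringsAsFactors = FALSE))
      }
      keep <- runif(nrow(pairs)) < p
      data.frame(pre = pairs$pre[keep], post = pairs$post[keep],
                 syn_class = rep(cls, sum(keep)), stringsAsFactors = FALSE)
    }
    # fixed draw order: intra-glomerular classes glomerulus by glomerulus,
    # then cross-glomerular LN->PN, then the SK strengths
    parts <- list()
    for (g in seq_len(ng)) {
      parts[[length(parts) + 1L]] <-
        draw(ordered_pairs(pn_ids[[g]], pn_ids[[g]], TRUE),
             params$p_PN_PN, "PN_PN")
      parts[[length(parts) + 1L]] <-
        draw(ordered_pairs(pn_ids[[g]], ln_ids[[g]], FALSE),
             params$p_PN_LN, "PN_LN")
      parts[[length(parts) + 1L]] <-
        draw(ordered_pairs(ln_ids[[g]], pn_ids[[g]], FALSE),
             params$p_LN_PN_intra, "LN_PN")
      parts[[length(parts) + 1L]] <-
        draw(ordered_pairs(ln_ids[[g]], ln_ids[[g]], TRUE),
             params$p_LN_LN, "LN_LN")
    }
    for (g in seq_len(ng)) {
      other_pns <- neurons$id[neurons$class == "PN" &
                                neurons$glomerulus != g]
      parts[[length(parts) + 1L]] <-
        draw(ordered_pairs(ln_ids[[g]], other_pns, FALSE),
             params$p_LN_PN_cross, "LN_PN")
    }
    sk_draw <- if (sk == "gaussian") {
      pmax(rnorm(n_pn, params$SK_mu, params$SK_sigma), 0)
    } else {
      rep(params$SK_mu, n_pn)
    }
    list(edges = do.call(rbind, parts), sk = sk_draw * params$scale_SK)
  })

  neurons$sk_strength <- c(edges$sk, rep(0, n_ln))
  structure(
    list(neurons = neurons, edges = edges$edges, params = params,
         seed = seed, sk_mode = sk),
    class = "al_network"
  )
}

#' Fixed-SK variant of the standard network
#'
#' Convenience wrapper for [al_network()] with `sk = "fixed"`: every PN gets
#' SK strength `SK_mu * scale_SK` exactly, while the synaptic wiring is drawn
#' as usual. This is the network used for SK conductance-strength sweeps,
#' where the standard strength is the mean of the Gaussian used in the
#' standard network.
#'
#' @inheritParams al_network
#' @return An `al_network` object.
#' @export
fixed_sk_network <- function(params = al_params(), seed = 1L) {
  al_network(params, seed, sk = "fixed")
}

# save/restore the global RNG so constructors with explicit seeds do not
# disturb the caller's stream
get_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' @export
print.al_network <- function(x, ...) {
  n <- table(x$neurons$class)
  cat(sprintf("Antennal lobe network: %d PN + %d LN in %d glomeruli (seed %d, SK %s)\n",
              n[["PN"]], n[["LN"]], x$params$n_glomeruli, x$seed, x$sk_mode))
  cat("  synapses:",
      paste(sprintf("%s=%d", names(table(x$edges$syn_class)),
                    as.integer(table(x$edges$syn_class))), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.al_network <- function(object, ...) {
  x <- object
  pn <- x$neurons[x$neurons$class == "PN", ]
  print(x)
  cat(sprintf("  SK strength: mean %.3f, sd %.3f, %d PNs clamped at 0\n",
              mean(pn$sk_strength), sd(pn$sk_strength),
              sum(pn$sk_strength == 0)))
  cross <- with(x$edges, syn_class == "LN_PN" &
                  x$neurons$glomerulus[pre] != x$neurons$glomerulus[post])
  cat(sprintf("  LN->PN synapses: %d intra-, %d cross-glomerular\n",
              sum(x$edges$syn_class == "LN_PN") - sum(cross), sum(cross)))
  invisible(x)
}

#' Tabular views of a network
#'
#' Return the neuron table and synapse edge list as plain data frames,
#' suitable for `write.csv()`.
#'
#' @param network an `al_network`.
#' @return `network_neurons`: data.frame (id, class, glomerulus,
#'   sk_strength). `network_edges`: data.frame (pre, post, syn_class).
#' @export
network_neurons <- function(network) {
  stopifnot(inherits(network, "al_network"))
  network$neurons
}

#' @rdname network_neurons
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "al_network"))
  network$edges
}
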