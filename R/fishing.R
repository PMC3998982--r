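#' Primary production required to sustain the catch
#'
#' Back-propagates the catch through the food web: the requirement vector
#' starts at the landings and discards Y and is repeatedly mapped through
#' M_ij = (Q_j / P_j) DC\[i,j\], converting demand on a predator's
#' production into demand on its prey's production; demand arriving at
#' primary producers and detritus pools is accumulated. The iteration
#' converges geometrically because trophic efficiency is below one at
#' every step; with `mode = "strict"` residual diet cycles are first
#' broken by deleting the minimum-flow arc of each cycle (identical
#' results on acyclic webs).
#'
#' @param m A balanced `food_web_model`.
#' @param net A `flow_network` (built when missing; supplies PP).
#' @param mode `"damped"` (default geometric propagation) or `"strict"`
#'   (cycle arcs removed before propagation).
#' @param tol,max_iter Convergence control for the propagation.
#' @return List with `PPRc` (t km-2 y-1, includes detritus uptake),
#'   `PPR_pct` (100 * PPRc / PP) and the diet matrix `DC` actually used.
#' @export
#' @examples
#' ppr_of_catch(fixture_chain3())$PPRc  # 2.5
ppr_of_catch <- function(m, net = build_flows(m), mode = c("damped", "strict"),
                         tol = 1e-12, max_iter = 10000L) {
  mode <- match.arg(mode)
  g <- m$groups
  n <- nrow(g)
  dc <- m$diet
  if (mode == "strict") dc <- break_diet_cycles(dc)
  q <- consumption(m)
  prod <- production(m)
  basal <- !is_consumer(m)   # producers and detritus accumulate demand
  qp <- ifelse(!basal & prod > 0, q / prod, 0)

  if (sum(g$Y) <= 0) {
    return(list(PPRc = 0, PPR_pct = 0, DC = dc))
  }
  demand <- g$Y
  accumulated <- sum(demand[basal])   # catch taken directly off basal groups
  demand[basal] <- 0
  total0 <- sum(g$Y)
  for (it in seq_len(max_iter)) {
    if (sum(demand) <= tol * total0) break
    required <- demand * qp                         # consumption needed per group
    arriving <- as.numeric(dc %*% required)         # demand on each prey's production
    accumulated <- accumulated + sum(arriving[basal])
    demand <- arriving
    demand[basal] <- 0
    if (it == max_iter) stop("PPR back-propagation did not converge; pathological cycle")
  }
  pprc <- accumulated
  list(PPRc = pprc, PPR_pct = if (net$PP_tot > 0) 100 * pprc / net$PP_tot else NA_real_,
       DC = dc)
}

# delete the minimum-flow arc of every remaining cycle in the diet graph
break_diet_cycles <- function(dc) {
  n <- nrow(dc)
  repeat {
    cyc <- find_cycle(dc > 0)
    if (is.null(cyc)) return(dc)
    # arcs along the cycle: prey -> predator edges (i, j) with dc[i, j] > 0
    arcs <- cbind(cyc, c(cyc[-1], cyc[1]))
    vals <- dc[arcs]
    kill <- arcs[which.min(vals), , drop = FALSE]
    message("removing diet cycle arc ", rownames(dc)[kill[1]], " -> ",
            colnames(dc)[kill[2]], " (DC = ", format(vals[which.min(vals)]), ")")
    dc[kill] <- 0
  }
}

# first directed cycle in adjacency matrix adj[i, j] (edge i -> j), or NULL
find_cycle <- function(adj) {
  n <- nrow(adj)
  color <- integer(n)      # 0 white, 1 on stack, 2 done
  parent <- integer(n)
  res <- NULL
  visit <- function(v, path) {
    color[v] <<- 1L
    for (w in which(adj[v, ])) {
      if (!is.null(res)) return()
      if (color[w] == 1L) {
        res <<- path[seq(match(w, path), length(path))]
      } else if (color[w] == 0L) {
        visit(w, c(path, w))
      }
    }
    color[v] <<- 2L
  }
  for (v in seq_len(n)) {
    if (color[v] == 0L && is.null(res)) visit(v, v)
  }
  res
}

#' Loss-in-production index
#'
#' Summarizes the footprint of the fishery as the fraction of secondary
#' production lost: L = PPRc * TE^(TLc - 1) / (PP * ln(1 / TE)), with TE
#' the mean transfer efficiency as a proportion. The primary production
#' appropriated by the catch (PPRc) is converted to equivalent production
#' at the mean trophic level of the catch and integrated over trophic
#' levels, giving zero at zero catch and a value strictly increasing in
#' PPRc.
#'
#' @param pprc Primary production required to sustain the catch,
#'   t km-2 y-1.
#' @param tlc Mean trophic level of the catch.
#' @param tem Mean transfer efficiency in percent (levels II-IV).
#' @param pp Total primary production, t km-2 y-1.
#' @return Scalar L; `NA` when `tem` is missing.
#' @export
l_index <- function(pprc, tlc, tem, pp) {
  if (is.na(tem) || is.na(tlc) || is.na(pprc)) return(NA_real_)
  if (pprc == 0) return(0)
  te <- tem / 100
  pprc * te^(tlc - 1) / (pp * log(1 / te))
}

#' Probability that the ecosystem is sustainably fished
#'
#' Maps the loss-in-production index onto a probability through a
#' monotone decreasing empirical calibration curve. The default curve is
#' a logistic in log10(L) with pluggable coefficients; it takes its
#' maximum at L = 0 and decreases strictly with L.
#'
#' @param l L index value(s).
#' @param calibration Coefficients from [psust_calibration()].
#' @return Probability in \[0, 1\], same length as `l`.
#' @export
p_sust <- function(l, calibration = psust_calibration()) {
  stopifnot(is.list(calibration))
  out <- rep(NA_real_, length(l))
  zero <- !is.na(l) & l <= 0
  pos <- !is.na(l) & l > 0
  out[zero] <- calibration$pmax
  out[pos] <- calibration$pmax /
    (1 + exp((log10(l[pos]) - log10(calibration$l50)) / calibration$slope))
  out
}

#' @rdname p_sust
#' @param pmax Probability at L = 0.
#' @param l50 L value at which the probability halves.
#' @param slope Logistic width in decades of L.
#' @export
psust_calibration <- function(pmax = 1, l50 = 0.05, slope = 0.25) {
  stopifnot(pmax > 0, pmax <= 1, l50 > 0, slope > 0)
  list(pmax = pmax, l50 = l50, slope = slope)
}

#' All fishing indicators of a model
#'
#' @param m A balanced `food_web_model`.
#' @param net,tl Optional precomputed flow network and trophic levels.
#' @param tem Mean transfer efficiency (percent); computed from the
#'   Lindeman spine when missing.
#' @param calibration P_sust calibration, see [psust_calibration()].
#' @return List `TC`, `TLc`, `PPRc`, `PPR_pct`, `L_index`, `P_sust`;
#'   all except `TC` are `NA` in unfished models.
#' @export
fishing_indicators <- function(m, net = build_flows(m),
                               tl = solve_trophic_levels(m),
                               tem = NULL, calibration = psust_calibration()) {
  tc <- sum(m$groups$Y)
  if (tc <= 0) {
    return(list(TC = 0, TLc = NA_real_, PPRc = NA_real_, PPR_pct = NA_real_,
                L_index = NA_real_, P_sust = NA_real_))
  }
  if (is.null(tem)) tem <- lindeman_spine(m, net, tl)$TEm
  tlc <- catch_tl(m, tl)
  ppr <- ppr_of_catch(m, net)
  l <- l_index(ppr$PPRc, tlc, tem, net$PP_tot)
  list(TC = tc, TLc = tlc, PPRc = ppr$PPRc, PPR_pct = ppr$PPR_pct,
       L_index = l, P_sust = p_sust(l, calibration))
}
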