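# Transition-path theory: committors, reactive flux, coarse-graining
# over metastable sets, and pathway decomposition by iterative
# bottleneck removal.

#' Forward committor of a Markov model
#'
#' Probability, started in each state, of reaching the sink set before
#' the source set; 0 on the source, 1 on the sink, and the solution of
#' the linear system (I - T_II) q_I = T_IB 1 on the interior.
#'
#' @param model `markov_model`.
#' @param source_set,sink_set disjoint integer vectors of state indices
#'   (positions within the model's active transition matrix).
#' @return numeric committor vector.
#' @export
forward_committor <- function(model, source_set, sink_set) {
  if (length(intersect(source_set, sink_set)) > 0)
    stop("source and sink sets must be disjoint")
  T <- model$T
  k <- nrow(T)
  q <- numeric(k)
  q[sink_set] <- 1
  interior <- setdiff(seq_len(k), c(source_set, sink_set))
  if (length(interior) > 0) {
    TI <- T[interior, interior, drop = FALSE]
    b <- rowSums(T[interior, sink_set, drop = FALSE])
    q[interior] <- solve(diag(length(interior)) - TI, b)
  }
  q
}

# Backward committor via the time-reversed chain.
backward_committor <- function(model, source_set, sink_set) {
  T <- model$T
  pi <- model$pi
  Tr <- t(T * pi) / pi       # Tr[i, j] = pi_j T_ji / pi_i
  Tr <- Tr / rowSums(Tr)
  k <- nrow(T)
  q <- numeric(k)
  q[source_set] <- 1
  interior <- setdiff(seq_len(k), c(source_set, sink_set))
  if (length(interior) > 0) {
    TI <- Tr[interior, interior, drop = FALSE]
    b <- rowSums(Tr[interior, source_set, drop = FALSE])
    q[interior] <- solve(diag(length(interior)) - TI, b)
  }
  q
}

#' Reactive flux network and pathway decomposition
#'
#' Transition-path theory between a source and a sink: the gross
#' reactive flux f_ij = pi_i q-_i T_ij q+_j (forward committor q+,
#' backward committor q-), its net (positive) part, the total reactive
#' flux (which is invariant across any cut separating source from
#' sink), optional coarse-graining over a metastable partition, and a
#' pathway decomposition of the net flux by iterative removal of the
#' strongest (widest-bottleneck) source-to-sink path.
#'
#' @param model `markov_model`.
#' @param source_set,sink_set disjoint state-index vectors.
#' @param partition optional `metastable_partition`; when given, fluxes
#'   and pathways are reported between metastable sets.
#' @param path_tol stop decomposing when the remaining flux falls
#'   below this fraction of the total.
#' @return object of class `flux_network`: `total_flux`, `committor`,
#'   `backward_committor`, `net_flux` (matrix, possibly coarse),
#'   `gross_flux`, `pathways` (list with `path`, `flux`, `percent`),
#'   `coarse` flag, and for coarse networks `source_group`/`sink_group`.
#' @export
coarse_fluxes <- function(model, source_set, sink_set, partition = NULL,
                          path_tol = 0.01) {
  qp <- forward_committor(model, source_set, sink_set)
  qm <- backward_committor(model, source_set, sink_set)
  T <- model$T
  pi <- model$pi
  k <- nrow(T)
  f <- (pi * qm) * T * matrix(qp, k, k, byrow = TRUE)
  diag(f) <- 0
  total <- sum(f[source_set, setdiff(seq_len(k), source_set), drop = FALSE])
  netf <- pmax(f - t(f), 0)
  if (!is.null(partition)) {
    lab <- partition$crisp
    m <- partition$m
    G <- matrix(0, m, m)
    for (a in seq_len(m)) for (b in seq_len(m)) if (a != b)
      G[a, b] <- sum(f[lab == a, lab == b, drop = FALSE])
    Gn <- pmax(G - t(G), 0)
    src <- unique(lab[source_set])
    snk <- unique(lab[sink_set])
    pw <- decompose_pathways(Gn, src, snk, total, path_tol)
    return(structure(list(total_flux = total, committor = qp,
                          backward_committor = qm, net_flux = Gn,
                          gross_flux = G, pathways = pw, coarse = TRUE,
                          source_group = src, sink_group = snk),
                     class = "flux_network"))
  }
  pw <- decompose_pathways(netf, source_set, sink_set, total, path_tol)
  structure(list(total_flux = total, committor = qp,
                 backward_committor = qm, net_flux = netf,
                 gross_flux = f, pathways = pw, coarse = FALSE),
            class = "flux_network")
}

# Widest-path (maximum bottleneck) search from any source to any sink
# on a flux matrix, by binary search over edge weights with BFS
# reachability; returns the best path found by a greedy Dijkstra-like
# relaxation on bottleneck capacity.
widest_path <- function(F, source_set, sink_set) {
  k <- nrow(F)
  cap <- rep(-Inf, k)
  prev <- rep(NA_integer_, k)
  cap[source_set] <- Inf
  visited <- rep(FALSE, k)
  repeat {
    u <- which(!visited & cap > -Inf)
    if (length(u) == 0) break
    u <- u[which.max(cap[u])]
    visited[u] <- TRUE
    if (u %in% sink_set) break
    for (v in which(F[u, ] > 0)) {
      c2 <- min(cap[u], F[u, v])
      if (c2 > cap[v]) {
        cap[v] <- c2
        prev[v] <- u
      }
    }
  }
  ends <- sink_set[is.finite(cap[sink_set]) & cap[sink_set] > 0]
  if (length(ends) == 0) return(NULL)
  end <- ends[which.max(cap[ends])]
  path <- end
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  list(path = path, bottleneck = cap[end])
}

# Iterative bottleneck-removal decomposition of a net flux matrix.
decompose_pathways <- function(Fnet, source_set, sink_set, total_flux,
                               path_tol = 0.01, max_paths = 50L) {
  F <- Fnet
  out <- list()
  remaining <- sum(F[source_set, , drop = FALSE])
  while (length(out) < max_paths) {
    wp <- widest_path(F, source_set, sink_set)
    if (is.null(wp) || wp$bottleneck <= path_tol * max(total_flux, 1e-300))
      break
    p <- wp$path
    for (i in seq_len(length(p) - 1L))
      F[p[i], p[i + 1L]] <- F[p[i], p[i + 1L]] - wp$bottleneck
    out[[length(out) + 1L]] <- list(
      path = p, flux = wp$bottleneck,
      percent = 100 * wp$bottleneck / total_flux)
  }
  out
}

#' @export
print.flux_network <- function(x, ...) {
  cat(sprintf("<flux_network: total flux %.4g, %d pathway(s)%s>\n",
              x$total_flux, length(x$pathways),
              if (x$coarse) ", coarse-grained" else ""))
  for (p in x$pathways)
    cat(sprintf("  %s : %.1f%%\n", paste(p$path, collapse = " -> "),
                p$percent))
  invisible(x)
}

#' Net flux across a cut
#'
#' Sum of net reactive flux over all edges crossing from a set
#' containing the source to its complement containing the sink; by
#' flux conservation this equals the total reactive flux for every
#' such cut.
#'
#' @param flux `flux_network` (fine-grained).
#' @param cut_set states on the source side of the cut.
#' @return numeric flux.
#' @export
flux_across_cut <- function(flux, cut_set) {
  other <- setdiff(seq_len(nrow(flux$net_flux)), cut_set)
  sum(flux$net_flux[cut_set, other, drop = FALSE]) -
    sum(flux$net_flux[other, cut_set, drop = FALSE])
}
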