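# Statistical-parsimony haplotype networks. Observed haplotypes are
# connected by single mutational steps (unobserved intermediates inserted
# on multi-step connections) up to a probabilistic connection limit in the
# Templeton-Crandall-Sing tradition: the largest number of steps at which
# a connection can still be assumed non-homoplasious with confidence
# `alpha`.

#' Statistical-parsimony connection limit
#'
#' Probability model: substitutions hit sites as independent Poisson events
#' under a Jukes-Cantor four-state chain. For two sequences of length `L`
#' differing at `j` sites, the per-site substitution intensity is
#' calibrated so the expected difference proportion equals `j/L`, and the
#' probability that the observed differences are parsimonious (each
#' differing site hit exactly once, no hidden or back mutation elsewhere)
#' is `P_j = (lam exp(-lam)/p_diff)^j * (exp(-lam)/(1-p_diff))^(L-j)`.
#' The limit is the largest `j` with `P_j >= alpha`, floored at one step.
#'
#' @param seq_len Number of compared sites (>= 1).
#' @param alpha Confidence level in (0.5, 1); default 0.95.
#' @return Integer number of mutational steps; nondecreasing in `seq_len`.
#' @export
parsimony_limit <- function(seq_len, alpha = 0.95) {
  if (seq_len < 1) abort("seq_len must be >= 1")
  if (alpha <= 0.5 || alpha >= 1) abort("alpha must be in (0.5, 1)")
  p <- parsimony_probability(1:seq_len, seq_len)
  j <- which(p >= alpha)
  # P_j is decreasing in j, so the largest qualifying j is the limit
  if (length(j) == 0L) return(1L)
  max(1L, max(j))
}

#' @rdname parsimony_limit
#' @param j Number of observed differences (vectorised).
#' @export
parsimony_probability <- function(j, seq_len) {
  vapply(j, function(jj) {
    if (jj >= seq_len * 0.74) return(0)
    q <- jj / seq_len
    lam <- -0.75 * log(1 - 4 * q / 3)
    pd <- 0.75 * (1 - exp(-4 * lam / 3))
    if (pd == 0) return(1)
    p1 <- lam * exp(-lam) / pd
    p0 <- exp(-lam) / (1 - pd)
    p1^jj * p0^(seq_len - jj)
  }, numeric(1))
}

#' Build a statistical-parsimony haplotype network
#'
#' Distance-ordered agglomerative construction: haplotype pairs are
#' examined in order of increasing Hamming distance up to the connection
#' limit; a multi-step connection inserts `d - 1` unobserved intermediate
#' nodes. At each distance level, connections are accepted between nodes
#' that were in different components when the level started (so
#' alternative equal-length connections are retained as reticulations);
#' single-step pairs always connect. Ties at equal distance are broken
#' toward the higher-frequency partner, then lexicographically.
#'
#' @param hap Haplotype table from [collapse_haplotypes()].
#' @param limit Connection limit in steps; default
#'   `parsimony_limit(nchar(seq))`.
#' @param alpha Confidence for the default limit.
#' @return A `haplotype_network`: list with `nodes` (tibble: `node`, `type`
#'   observed/inferred, `n`, `by_site` list column), `edges` (tibble:
#'   `from`, `to`, `level` = Hamming distance of the connection that
#'   created the edge; every edge is one mutational step), `limit`.
#' @export
build_network <- function(hap, limit = NULL, alpha = 0.95) {
  n_hap <- nrow(hap)
  L <- nchar(hap$seq[1])
  if (is.null(limit)) limit <- parsimony_limit(L, alpha)
  m <- do.call(rbind, strsplit(hap$seq, ""))
  dmat <- pairwise_diffs(m)
  nodes <- tibble(node = hap$haplotype, type = "observed",
                  n = hap$n, by_site = hap$by_site)
  edges <- tibble(from = character(0), to = character(0), level = integer(0))
  comp <- seq_len(n_hap)          # union-find over observed haplotypes
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  inter_count <- 0L
  if (n_hap > 1) {
    pairs <- which(upper.tri(dmat), arr.ind = TRUE)
    pd <- dmat[upper.tri(dmat)]
    for (d in sort(unique(pd[pd <= limit]))) {
      at_d <- which(pd == d)
      # tie-break: higher combined partner frequency first, then node ids
      key_freq <- hap$n[pairs[at_d, 1]] + hap$n[pairs[at_d, 2]]
      key_lex <- paste(hap$haplotype[pairs[at_d, 1]],
                       hap$haplotype[pairs[at_d, 2]])
      at_d <- at_d[order(-key_freq, key_lex)]
      comp_before <- vapply(seq_len(n_hap), find, integer(1))
      for (idx in at_d) {
        i <- pairs[idx, 1]; j <- pairs[idx, 2]
        if (d > 1 && comp_before[i] == comp_before[j]) next
        # chain of d single-step edges through d-1 inferred intermediates
        chain <- hap$haplotype[i]
        if (d > 1) {
          inter <- paste0("m", inter_count + seq_len(d - 1L))
          inter_count <- inter_count + d - 1L
          chain <- c(chain, inter)
        }
        chain <- c(chain, hap$haplotype[j])
        edges <- bind_rows(edges,
          tibble(from = chain[-length(chain)], to = chain[-1], level = d))
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[rj] <- ri
      }
    }
  }
  # rebuild node table cleanly (observed + all intermediates referenced)
  inferred <- setdiff(unique(c(edges$from, edges$to)), hap$haplotype)
  nodes <- bind_rows(
    tibble(node = hap$haplotype, type = "observed", n = hap$n,
           by_site = hap$by_site),
    tibble(node = inferred, type = "inferred", n = rep(0L, length(inferred)),
           by_site = rep(list(NULL), length(inferred)))
  )
  membership <- rep(NA_integer_, nrow(nodes))
  g <- as_igraph_nodes_edges(nodes, edges)
  membership <- igraph::components(g)$membership[nodes$node]
  structure(list(nodes = mutate(nodes, component = as.integer(membership)),
                 edges = edges, limit = as.integer(limit),
                 n_seq = attr(hap, "n_seq") %||% sum(hap$n)),
            class = "haplotype_network")
}

as_igraph_nodes_edges <- function(nodes, edges) {
  igraph::graph_from_data_frame(
    d = as.data.frame(edges[c("from", "to")]),
    directed = FALSE,
    vertices = data.frame(name = nodes$node)
  )
}

#' Convert a haplotype network to igraph / GraphML
#'
#' @param net A `haplotype_network`.
#' @return An igraph object with node attributes `type`, `count` and one
#'   `loc_<site>` attribute per locality, and edge attribute `steps` (= 1).
#' @export
as_igraph <- function(net) {
  g <- as_igraph_nodes_edges(net$nodes, net$edges)
  igraph::V(g)$type <- net$nodes$type
  igraph::V(g)$count <- net$nodes$n
  sites <- sort(unique(unlist(purrr::map(net$nodes$by_site, names))))
  for (s in sites) {
    vals <- map_int(net$nodes$by_site, function(bs) {
      if (is.null(bs) || !s %in% names(bs)) 0L else as.integer(bs[[s]])
    })
    g <- igraph::set_vertex_attr(g, paste0("loc_", s), value = vals)
  }
  igraph::E(g)$steps <- 1L
  g
}

#' @rdname as_igraph
#' @param path Output path for GraphML.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("<haplotype_network> ", sum(x$nodes$type == "observed"),
      " observed + ", sum(x$nodes$type == "inferred"),
      " inferred haplotypes, ", nrow(x$edges), " edges, ",
      max(x$nodes$component), " component(s); limit ", x$limit,
      " steps\n", sep = "")
  invisible(x)
}

#' Haplotype sharing across localities
#'
#' Lists haplotypes observed at two or more localities and tests the
#' association between haplotype identity and locality with a chi-square
#' statistic on the haplotype-by-locality count table against a
#' permutation null (locality labels permuted over individuals).
#'
#' @param hap Haplotype table from [collapse_haplotypes()] (or a
#'   `haplotype_network`).
#' @param reps Permutations (default 999).
#' @param seed Optional RNG seed.
#' @return List with `shared` (tibble: `haplotype`, `site`, `count` for
#'   haplotypes at >= 2 localities), `chisq`, `p_value`, `n_localities`.
#' @export
locality_sharing <- function(hap, reps = 999L, seed = NULL) {
  if (inherits(hap, "haplotype_network")) {
    hap <- filter(hap$nodes, .data$type == "observed") |>
      rename(haplotype = "node")
  }
  if (!is.null(seed)) set.seed(seed)
  long <- bind_rows(purrr::map2(hap$haplotype, hap$by_site, function(h, bs) {
    if (is.null(bs)) return(NULL)
    tibble(haplotype = h, site = names(bs), count = as.integer(bs))
  }))
  n_loc <- length(unique(long$site))
  shared <- long |>
    group_by(.data$haplotype) |>
    filter(dplyr::n() >= 2) |>
    ungroup() |>
    arrange(.data$haplotype, .data$site)
  if (n_loc < 2) {
    return(list(shared = shared[0, ], chisq = NA_real_, p_value = NA_real_,
                n_localities = n_loc))
  }
  indiv <- tibble(
    haplotype = rep(long$haplotype, long$count),
    site = rep(long$site, long$count)
  )
  stat <- function(sites) {
    suppressWarnings(unname(
      chisq.test(table(indiv$haplotype, sites), correct = FALSE)$statistic))
  }
  obs <- stat(indiv$site)
  perm <- vapply(seq_len(reps), function(r) stat(sample(indiv$site)),
                 numeric(1))
  list(shared = shared, chisq = obs,
       p_value = (sum(perm >= obs) + 1) / (reps + 1),
       n_localities = n_loc)
}

#' Plot a haplotype network
#'
#' Simple ggplot rendering: observed haplotypes as circles with area
#' proportional to frequency, inferred intermediates as small black dots,
#' single-step edges as segments.
#'
#' @param object A `haplotype_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.haplotype_network <- function(object, ...) {
  g <- as_igraph(object)
  set.seed(1L)
  xy <- igraph::layout_with_fr(g)
  nd <- mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  ed <- object$edges |>
    left_join(select(nd, "node", "x", "y"), by = c(from = "node")) |>
    rename(x0 = "x", y0 = "y") |>
    left_join(select(nd, "node", "x", "y"), by = c(to = "node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
      ggplot2::aes(x = .data$x0, y = .data$y0,
                   xend = .data$x, yend = .data$y), colour = "grey50") +
    ggplot2::geom_point(data = filter(nd, .data$type == "inferred"),
      ggplot2::aes(.data$x, .data$y), size = 1, colour = "black") +
    ggplot2::geom_point(data = filter(nd, .data$type == "observed"),
      ggplot2::aes(.data$x, .data$y, size = .data$n), shape = 21,
      fill = "steelblue") +
    ggplot2::scale_size_area(max_size = 10) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "frequency")
}
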