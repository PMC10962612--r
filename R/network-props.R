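#' Node-removal fragility of an association network
#'
#' Simulates system collapse by removing nodes one at a time.  For each
#' repeat, a uniformly random removal order is drawn (or, with
#' `mode = "degree"`, nodes are removed in descending initial-degree order,
#' ties by id); after each removal the fraction of the remaining nodes
#' lying in the giant (largest) component is recorded.  Curves are averaged
#' over repeats on the removed-fraction grid i/m, i = 0..m-1, and
#' summarized by the trapezoid AUC normalized to [0, 1].  A more robust
#' network keeps its giant component longer and has a larger AUC.
#'
#' @param x an [AssociationNetwork-class] with at least 2 nodes.
#' @param repeats number of random removal orders to average (default 100;
#'   a single deterministic pass is used for `mode = "degree"`).
#' @param seed RNG seed for the removal orders.
#' @param mode `"random"` (default) or `"degree"` (targeted attack).
#' @return a [FragilityCurve-class].
#' @export
fragility <- function(x, repeats = 100L, seed = NULL,
                      mode = c("random", "degree")) {
    mode <- match.arg(mode)
    if (repeats < 1L) stop("repeats must be >= 1")
    m <- length(x@nodes)
    if (m < 2L) stop("at least 2 nodes required")
    g <- asIgraph(x)
    if (mode == "degree") {
        deg <- igraph::degree(g)
        orders <- list(order(-deg, igraph::V(g)$name))
        repeats <- 1L
    } else {
        orders <- .withSeed(seed,
            replicate(repeats, sample.int(m), simplify = FALSE))
    }
    grid <- (seq_len(m) - 1L) / m
    acc <- numeric(m)
    for (ord in orders) {
        cur <- g
        giant <- numeric(m)
        giant[1L] <- max(igraph::components(cur)$csize) / m
        for (i in seq_len(m - 1L)) {
            cur <- igraph::delete_vertices(cur, x@nodes[ord[i]])
            giant[i + 1L] <- max(igraph::components(cur)$csize) / (m - i)
        }
        acc <- acc + giant
    }
    curve <- acc / repeats
    auc <- .trapz(grid, curve) / (grid[m] - grid[1L])
    new("FragilityCurve", fractions = grid, giantFraction = curve,
        repeats = as.integer(repeats),
        seed = if (is.null(seed)) NA_real_ else as.numeric(seed),
        auc = auc, mode = mode)
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
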