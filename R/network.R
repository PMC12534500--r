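# Weighted graph metrics of unthresholded PLV networks, in the
# brain-connectivity-toolbox lineage (Rubinov & Sporns 2010): Onnela
# geometric-mean clustering, inverse-weight connection lengths, Dijkstra
# shortest paths, global and local efficiency. The full weighted matrix is
# consumed as-is — no thresholding anywhere.

# Coerce a PLVMatrix or plain symmetric matrix to a weight matrix with the
# diagonal (self-loops) removed.
asWeightMatrix <- function(x) {
  w <- if (is(x, "PLVMatrix")) plvValues(x) else as.matrix(x)
  if (nrow(w) != ncol(w)) stop("weight matrix must be square")
  if (any(w < 0)) stop("weights must be non-negative")
  if (max(abs(w - t(w))) > 1e-9) stop("weight matrix must be symmetric")
  diag(w) <- 0
  w
}

#' Weighted clustering coefficient (Onnela)
#'
#' Onnela geometric-mean formulation on weights normalized by the
#' off-diagonal maximum: \eqn{C_i = \sum_{j,h} (\hat w_{ij} \hat w_{ih}
#' \hat w_{jh})^{1/3} / (k_i (k_i - 1))}, where the degree \eqn{k_i} counts
#' nonzero weights. Nodes with fewer than two neighbours get \eqn{C_i = 0}.
#'
#' @param x a \linkS4class{PLVMatrix} or symmetric non-negative matrix
#'   (diagonal ignored).
#' @return list with \code{perNode} (named numeric) and \code{mean}.
#' @export
weightedClustering <- function(x) {
  w <- asWeightMatrix(x)
  mx <- max(w)
  wh <- if (mx > 0) (w / mx)^(1 / 3) else w
  cyc3 <- diag(wh %*% wh %*% wh)
  k <- rowSums(w > 0)
  cc <- ifelse(k >= 2, cyc3 / (k * (k - 1)), 0)
  names(cc) <- rownames(w)
  list(perNode = cc, mean = mean(cc))
}

# All-pairs shortest-path distance matrix over connection lengths 1/w
# (zero weight = no edge), by Dijkstra.
shortestPathLengths <- function(w) {
  n <- nrow(w)
  lw <- w
  lw[w > 0] <- 1 / w[w > 0]
  g <- igraph::graph_from_adjacency_matrix(lw, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(D) <- dimnames(w)
  D
}

#' Characteristic path length and global efficiency
#'
#' Connection lengths are inverse weights (1/w; zero weight means no
#' edge); d_ij are Dijkstra shortest-path distances. CPL is the mean of
#' d_ij over connected ordered pairs i != j (disconnected pairs are
#' excluded from CPL and counted); GE is the mean of 1/d_ij over all
#' ordered pairs i != j, with disconnected pairs contributing 0.
#'
#' @param x a \linkS4class{PLVMatrix} or symmetric non-negative matrix.
#' @return list with \code{cpl}, \code{ge}, \code{nDisconnectedPairs}.
#' @export
pathMetrics <- function(x) {
  w <- asWeightMatrix(x)
  n <- nrow(w)
  if (n < 2) stop("path metrics need at least 2 nodes")
  D <- shortestPathLengths(w)
  off <- D[row(D) != col(D)]
  finite <- is.finite(off)
  cpl <- if (any(finite)) mean(off[finite]) else NA_real_
  inv <- ifelse(finite, 1 / off, 0)
  list(cpl = cpl, ge = mean(inv),
       nDisconnectedPairs = sum(!finite))
}

#' Weighted local efficiency
#'
#' For each node i with neighbourhood N(i) (nonzero weights) of size
#' \eqn{k_i \ge 2}: \eqn{E_{loc}(i) = \sum_{j,h \in N(i), j \ne h}
#' (\hat w_{ij} \hat w_{ih} [d_{jh}(N_i)]^{-1})^{1/3} / (k_i (k_i - 1))},
#' where \eqn{d_{jh}(N_i)} is the shortest-path distance within the
#' subgraph induced by N(i) over inverse normalized weights. Nodes with
#' \eqn{k_i < 2} get 0. Weights are normalized by the off-diagonal maximum
#' of the full matrix.
#'
#' @param x a \linkS4class{PLVMatrix} or symmetric non-negative matrix.
#' @return list with \code{perNode} (named numeric) and \code{mean}.
#' @export
localEfficiency <- function(x) {
  w <- asWeightMatrix(x)
  mx <- max(w)
  wn <- if (mx > 0) w / mx else w
  n <- nrow(wn)
  le <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(wn[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- wn[nb, nb, drop = FALSE]
    Dsub <- shortestPathLengths(sub)
    invd <- ifelse(is.finite(Dsub) & Dsub > 0, 1 / Dsub, 0)
    sw <- wn[i, nb]
    term <- (outer(sw, sw) * invd)^(1 / 3)
    diag(term) <- 0
    le[i] <- sum(term) / (k * (k - 1))
  }
  names(le) <- rownames(w)
  list(perNode = le, mean = mean(le))
}

#' All weighted network metrics of a PLV matrix
#'
#' Computes the mean weighted clustering coefficient (CC), characteristic
#' path length (CPL), global efficiency (GE) and mean local efficiency
#' (LE) of the unthresholded weighted network, plus node-wise CC and LE.
#'
#' @param x a \linkS4class{PLVMatrix} or symmetric non-negative matrix.
#' @param meta metadata carried into the output.
#' @return list with \code{cc}, \code{cpl}, \code{ge}, \code{le},
#'   \code{perNode} (data.frame node, cc, le),
#'   \code{nDisconnectedPairs}, \code{meta}.
#' @examples
#' w <- matrix(1, 4, 4); diag(w) <- 0
#' networkMetrics(w)[c("cc", "cpl", "ge", "le")]
#' @export
networkMetrics <- function(x, meta = list()) {
  cc <- weightedClustering(x)
  pm <- pathMetrics(x)
  le <- localEfficiency(x)
  nodes <- names(cc$perNode)
  if (is.null(nodes)) nodes <- as.character(seq_along(cc$perNode))
  list(cc = cc$mean, cpl = pm$cpl, ge = pm$ge, le = le$mean,
       perNode = data.frame(node = nodes, cc = unname(cc$perNode),
                            le = unname(le$perNode),
                            stringsAsFactors = FALSE),
       nDisconnectedPairs = pm$nDisconnectedPairs,
       meta = meta)
}
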