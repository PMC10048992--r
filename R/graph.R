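# Graph-based high-order feature embedding (GFE).
#
# Part descriptors pooled under the attention maps become graph nodes. A
# cosine-similarity adjacency (plus self-loops) is symmetrically
# normalized and one graph-convolution layer embeds the node bank:
#
#   G = ReLU(D^(-1/2) (A + I) D^(-1/2) K W)
#
# One embedding per pyramid level (plus a base-level embedding of the
# stage-4 trunk) is produced; an adaptive attention over levels weighs the
# per-level class scores into the fused prediction
#
#   C = sum_m I_m softmax(head_m(G_m)),  I = softmax(tanh(W_m g_m + b_m)).

#' Part feature bank
#'
#' @param nodes `N x D` matrix of part descriptors (rows = nodes).
#' @param level pyramid level the bank came from (0 = trunk).
#' @return object of class `fgr_part_bank`.
#' @export
fgr_part_bank <- function(nodes, level = 0L) {
  nodes <- as.matrix(nodes)
  stopifnot(nrow(nodes) >= 1L, all(is.finite(nodes)))
  structure(list(nodes = nodes, level = as.integer(level)),
            class = "fgr_part_bank")
}

#' Attention-weighted part pooling
#'
#' Node `i` is the attention-weighted spatial sum `sum_p Fd_i(p) X(p, .)`
#' of the stage features under part map `i`. Because each part map sums to
#' 1, a uniform map yields the global average feature and a single-hot map
#' yields the feature vector at that pixel.
#'
#' When `max_nodes` is smaller than the number of part channels, the most
#' concentrated maps (largest single-pixel attention mass) are kept; this
#' bounds graph cost while retaining the most part-like channels.
#'
#' @param att [fgr_attention()] maps (`C' x H x W`).
#' @param feat feature map with the same spatial size (`H x W x D`).
#' @param max_nodes node-count cap (default 32).
#' @return [fgr_part_bank()] with `min(C', max_nodes)` rows of length `D`.
#' @export
fgr_part_pooling <- function(att, feat, max_nodes = 32L) {
  da <- dim(att$maps); df <- dim(feat)
  if (!all(da[2:3] == df[1:2])) {
    stop("part_pooling: attention is ", da[2], "x", da[3],
         " but features are ", df[1], "x", df[2])
  }
  Cp <- da[1L]
  A <- matrix(att$maps, Cp, da[2L] * da[3L])   # C' x HW (spatial col-major)
  X <- as_position_matrix(unclass(feat))       # HW x D, same ordering
  nodes <- A %*% X
  if (Cp > max_nodes) {
    peak <- apply(A, 1L, max)
    keep <- sort(order(peak, decreasing = TRUE)[seq_len(max_nodes)])
    nodes <- nodes[keep, , drop = FALSE]
  }
  fgr_part_bank(nodes, att$level)
}

#' Similarity adjacency with self-loops
#'
#' `A_ij` is the cosine similarity of the transformed node features
#' `tau(f_i)`, `tau(f_j)`; the returned matrix is `A + I`. A zero-norm
#' transformed node contributes similarity 0 to every pair it is in
#' (including its own diagonal of `A`), never NaN.
#'
#' @param bank [fgr_part_bank()].
#' @param tau optional `D x Dt` linear transform applied to the rows before
#'   the similarity (the 1x1 dimension-transform convolution); `NULL` for
#'   identity.
#' @param nonneg clamp negative similarities to 0 before adding the
#'   self-loops. The raw cosine adjacency can produce negative node
#'   degrees, which the symmetric normalization cannot handle; the model
#'   pipeline treats anti-correlated parts as simply unconnected.
#' @return `N x N` symmetric matrix `A + I`.
#' @export
fgr_adjacency <- function(bank, tau = NULL, nonneg = FALSE) {
  K <- bank$nodes
  Tn <- if (is.null(tau)) K else K %*% tau
  nrm <- sqrt(rowSums(Tn^2))
  S <- Tn %*% t(Tn)
  denom <- outer(nrm, nrm)
  A <- ifelse(denom > 0, S / ifelse(denom > 0, denom, 1), 0)
  A <- (A + t(A)) / 2            # enforce exact symmetry against fp noise
  if (nonneg) A <- pmax(A, 0)
  A + diag(nrow(K))
}

#' Graph propagation layer
#'
#' `G = ReLU(D^(-1/2) A~ D^(-1/2) K W)` with `D_ii = sum_j A~_ij`. Node
#' count is preserved; feature width becomes `ncol(W)`.
#'
#' @param bank [fgr_part_bank()] (`N x D`).
#' @param a_tilde `N x N` adjacency with self-loops.
#' @param W `D x Dh` projection.
#' @return `N x Dh` matrix of embedded node features.
#' @export
fgr_graph_propagate <- function(bank, a_tilde, W) {
  K <- bank$nodes
  stopifnot(nrow(a_tilde) == nrow(K), ncol(a_tilde) == nrow(K),
            nrow(W) == ncol(K))
  deg <- rowSums(a_tilde)
  if (any(deg <= 0)) stop("graph_propagate: zero row degree in A~")
  dm <- 1 / sqrt(deg)
  S <- a_tilde * outer(dm, dm)
  relu(S %*% K %*% W)
}

#' Adaptive level attention
#'
#' Per level `m`: node scores `eta_mi = tanh(W_m g_mi + b_m)` are averaged
#' over nodes into a level scalar, and the scalars are softmax-normalized
#' into weights `I_m` summing to 1.
#'
#' @param G_levels list of `N_m x Dh` embedded node matrices.
#' @param params optional list with per-level `w` (length-`Dh` vector) and
#'   `b` (scalar); a single shared `w`,`b` pair is recycled. `NULL` draws
#'   nothing and uses `w = 1/Dh`, `b = 0` (deterministic default).
#' @return object of class `fgr_level_weights`: list with `I` (weights) and
#'   `eta` (pre-softmax level scores).
#' @export
fgr_level_attention <- function(G_levels, params = NULL) {
  stopifnot(length(G_levels) >= 1L)
  eta <- vapply(seq_along(G_levels), function(m) {
    G <- G_levels[[m]]
    p <- level_att_params(params, m, ncol(G))
    mean(tanh(G %*% p$w + p$b))
  }, 0)
  I <- fgr_softmax(eta)
  structure(list(I = I, eta = eta), class = "fgr_level_weights")
}

level_att_params <- function(params, m, Dh) {
  if (is.null(params)) return(list(w = rep(1 / Dh, Dh), b = 0))
  p <- if (!is.null(params$w)) params else params[[min(m, length(params))]]
  list(w = p$w, b = p$b)
}

#' Fused class score
#'
#' `C = sum_m I_m softmax(head_m(mean_nodes(G_m)))`: each level's embedding
#' is mean-pooled over nodes, pushed through its linear classifier head,
#' softmaxed, and the per-level distributions are mixed with the level
#' weights. The result is a probability vector for arbitrary nonnegative
#' weights summing to 1.
#'
#' @param G_levels list of embedded node matrices.
#' @param weights [fgr_level_attention()] output (or list with element `I`).
#' @param heads list of heads, one per level, each a list with `W`
#'   (`Dh x K`) and `b` (length `K`).
#' @return length-`K` probability vector.
#' @export
fgr_fused_score <- function(G_levels, weights, heads) {
  if (length(heads) != length(G_levels)) {
    stop("fused_score: ", length(G_levels), " levels but ", length(heads),
         " heads")
  }
  I <- weights$I
  stopifnot(length(I) == length(G_levels))
  out <- NULL
  for (m in seq_along(G_levels)) {
    g <- colMeans(G_levels[[m]])
    z <- drop(g %*% heads[[m]]$W + heads[[m]]$b)
    p <- fgr_softmax(z)
    out <- if (is.null(out)) I[m] * p else out + I[m] * p
  }
  out
}
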