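# Molecular-network construction and activity-label voting.

#' Build a thresholded activity network
#'
#' Connects labeled compounds whose pairwise similarity is at or above the
#' threshold. With \code{topK} set, an optional edge-filtering step keeps
#' an edge only when at least one of its endpoints ranks the other among
#' its \code{topK} most similar passing neighbors (union rule; ties in the
#' k-th similarity broken by ascending compound id). Compounds without a
#' conclusive label are excluded before construction.
#'
#' @param simMat a \linkS4class{SimilarityMatrix}.
#' @param labels named 0/1 vector (active = 1) over a subset of the matrix
#'   ids; see [labelVector()].
#' @param threshold similarity threshold in \code{[0, 1]}.
#' @param topK per-node cap on retained edges (default \code{NA}: keep all
#'   passing edges; the conventional cap is 6).
#' @return an \linkS4class{ActivityNetwork}.
#' @export
buildNetwork <- function(simMat, labels, threshold, topK = NA_integer_) {
    stopifnot(is(simMat, "SimilarityMatrix"),
              threshold >= 0, threshold <= 1)
    if (!is.na(topK) && topK < 1) stop("topK must be >= 1 when given")
    ids <- intersect(compoundIds(simMat), names(labels))
    if (!length(ids))
        stop("no overlap between similarity matrix ids and labeled ids")
    lab <- as.integer(labels[ids])
    if (!all(lab %in% c(0L, 1L))) stop("labels must be 0/1")
    ids <- sort(ids)
    lab <- as.integer(labels[ids])
    v <- similarityValues(simMat)[ids, ids, drop = FALSE]
    n <- length(ids)
    pass <- which(upper.tri(v) & v >= threshold, arr.ind = TRUE)
    edges <- data.frame(from = ids[pass[, 1L]], to = ids[pass[, 2L]],
                        weight = v[pass], stringsAsFactors = FALSE)
    if (!is.na(topK) && nrow(edges)) {
        inTop <- function(node, other) {
            nb <- c(edges$to[edges$from == node], edges$from[edges$to == node])
            w <- v[node, nb]
            ord <- nb[order(-w, nb)]
            other %in% utils::head(ord, topK)
        }
        keep <- vapply(seq_len(nrow(edges)), function(e)
            inTop(edges$from[e], edges$to[e]) ||
            inTop(edges$to[e], edges$from[e]), logical(1))
        edges <- edges[keep, , drop = FALSE]
    }
    rownames(edges) <- NULL
    new("ActivityNetwork",
        nodes = data.frame(id = ids, label = lab, stringsAsFactors = FALSE),
        edges = edges, threshold = as.numeric(threshold),
        topK = as.integer(topK))
}

# neighbor ids + edge weights of one node
.neighbors <- function(net, node) {
    ed <- net@edges
    isF <- ed$from == node
    isT <- ed$to == node
    data.frame(id = c(ed$to[isF], ed$from[isT]),
               weight = c(ed$weight[isF], ed$weight[isT]),
               stringsAsFactors = FALSE)
}

#' Activity vote for one node
#'
#' Predicts a node's probability of activity from its direct neighbors'
#' labels: majority voting divides the number of active neighbors by the
#' number of neighbors; weighted voting divides the summed similarity to
#' active neighbors by the summed similarity to all neighbors. An isolated
#' node gets no probability (\code{connected = FALSE}).
#'
#' @param net an \linkS4class{ActivityNetwork}.
#' @param node compound id present in the network.
#' @param scheme \code{"majority"} or \code{"weighted"}.
#' @return data.frame row with columns \code{id}, \code{probability}
#'   (\code{NA} when isolated), \code{connected}.
#' @examples
#' # a feature connected to 171 database spectra of which 39 are active
#' # receives majority-vote activity probability 39/171 = 0.228
#' @export
vote <- function(net, node, scheme = c("majority", "weighted")) {
    scheme <- match.arg(scheme)
    stopifnot(is(net, "ActivityNetwork"))
    if (!node %in% net@nodes$id) stop("unknown node: ", node)
    nb <- .neighbors(net, node)
    if (!nrow(nb))
        return(data.frame(id = node, probability = NA_real_,
                          connected = FALSE, stringsAsFactors = FALSE))
    nbLab <- net@nodes$label[match(nb$id, net@nodes$id)]
    p <- if (scheme == "majority") mean(nbLab)
         else sum(nb$weight[nbLab == 1L]) / sum(nb$weight)
    data.frame(id = node, probability = p, connected = TRUE,
               stringsAsFactors = FALSE)
}

#' Leave-one-out network predictions
#'
#' Builds the network once from the full similarity matrix and predicts
#' every node from its neighbors' true labels; a node's own label never
#' enters its prediction (there are no self-edges).
#'
#' @inheritParams buildNetwork
#' @param voting \code{"majority"} or \code{"weighted"}.
#' @return data.frame with columns \code{id}, \code{probability},
#'   \code{connected}, one row per labeled node.
#' @export
looPredict <- function(simMat, labels, threshold, topK = NA_integer_,
                       voting = c("majority", "weighted")) {
    voting <- match.arg(voting)
    if (sum(names(labels) %in% compoundIds(simMat)) < 2L)
        stop("need at least 2 labeled nodes")
    net <- buildNetwork(simMat, labels, threshold, topK)
    out <- do.call(rbind, lapply(net@nodes$id, vote, net = net,
                                 scheme = voting))
    rownames(out) <- NULL
    out
}

#' Grid search over network hyperparameters
#'
#' Scores every combination of similarity metric, threshold, edge
#' filtering and voting scheme by leave-one-out prediction and the
#' modified ROC-AUC (which penalizes configurations that leave many nodes
#' unconnected), and ranks the grid by decreasing score. Ties are broken
#' deterministically by metric name, ascending threshold, then voting
#' scheme.
#'
#' @param matrices named list of \linkS4class{SimilarityMatrix} objects,
#'   one per metric.
#' @param labels named 0/1 vector (active = 1).
#' @param grid data.frame with columns \code{metric}, \code{threshold},
#'   \code{topK} (\code{NA} for no edge filtering) and \code{voting}. If
#'   omitted, the default grid crosses all supplied metrics with
#'   thresholds 0.0-0.9 (step 0.1), both voting schemes, and edge
#'   filtering off and at 6.
#' @return the grid with an \code{mrocAuc} column, ranked best-first.
#' @export
optimizeHyperparams <- function(matrices, labels, grid = NULL) {
    stopifnot(is.list(matrices), length(matrices) > 0,
              !is.null(names(matrices)))
    if (is.null(grid))
        grid <- expand.grid(metric = names(matrices),
                            threshold = seq(0, 0.9, by = 0.1),
                            topK = c(NA_integer_, 6L),
                            voting = c("majority", "weighted"),
                            stringsAsFactors = FALSE)
    stopifnot(nrow(grid) > 0,
              all(c("metric", "threshold", "topK", "voting") %in% names(grid)))
    grid$mrocAuc <- vapply(seq_len(nrow(grid)), function(k) {
        m <- matrices[[grid$metric[k]]]
        if (is.null(m)) stop("no similarity matrix for metric ", grid$metric[k])
        preds <- looPredict(m, labels, grid$threshold[k], grid$topK[k],
                            grid$voting[k])
        mrocAuc(preds, labels)
    }, numeric(1))
    o <- order(-grid$mrocAuc, grid$metric, grid$threshold, grid$voting)
    out <- grid[o, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Export a network as an edge list or GraphML
#'
#' @param net an \linkS4class{ActivityNetwork}.
#' @param path output file path.
#' @param format \code{"edgelist"} (tab-delimited id_i, id_j, weight) or
#'   \code{"graphml"}.
#' @return \code{path}, invisibly.
#' @export
exportNetwork <- function(net, path, format = c("edgelist", "graphml")) {
    format <- match.arg(format)
    stopifnot(is(net, "ActivityNetwork"))
    if (format == "edgelist") {
        utils::write.table(net@edges, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else {
        g <- igraph::graph_from_data_frame(
            net@edges, directed = FALSE,
            vertices = data.frame(name = net@nodes$id,
                                  label = net@nodes$label))
        igraph::write_graph(g, path, format = "graphml")
    }
    invisible(path)
}
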