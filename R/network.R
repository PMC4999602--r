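#' Build a dose network from arm-level trial data
#'
#' Constructs the arm-level data container used by every model in the
#' package.  Each row of `data` is one trial arm: a study label, an agent
#' label, a dose in the agent's raw units, the number of responders and the
#' number analysed.  Doses are standardized at load time to multiples of
#' each agent's common dose, so that dose-response parameters are
#' comparable across agents; models only ever see the standardized dose.
#'
#' Within each study the reference arm (arm 1) is the placebo arm if one is
#' present, otherwise the arm whose treatment comes first in the network's
#' treatment ordering.  All relative effects are defined against arm 1, so
#' this tie-break is deterministic and recorded.
#'
#' @param data data.frame with columns `study`, `agent`, `dose`,
#'   `responders`, `sample_size`.  One row per arm.
#' @param common_doses named numeric vector mapping each active agent to its
#'   common dose (raw units), or a data.frame with columns `agent` and
#'   `common_dose`.  Not needed when `standardized = TRUE`.
#' @param reference label of the network reference agent (dose 0); default
#'   `"placebo"`.
#' @param standardized logical; if `TRUE` the `dose` column is already in
#'   multiples of the common dose and `common_doses` is ignored.
#' @return An object of class `dose_network`: a list with elements `arms`
#'   (validated arm table with `dose_std`), `studies`, `agents` (reference
#'   first), `reference`, `common_doses` and `coding` (`"split"` or
#'   `"lumped"`).
#' @seealso [read_dose_network()], [network_summary()], [lump_doses()],
#'   [split_doses()]
#' @examples
#' arms <- data.frame(
#'   study = rep(c("s1", "s2"), each = 2),
#'   agent = c("placebo", "sumatriptan", "placebo", "sumatriptan"),
#'   dose = c(0, 100, 0, 50),
#'   responders = c(10, 25, 8, 18),
#'   sample_size = c(50, 50, 40, 45))
#' net <- dose_network(arms, common_doses = c(sumatriptan = 50))
#' net$arms$dose_std  # 0, 2, 0, 1
#' @export
dose_network <- function(data, common_doses = NULL, reference = "placebo",
                         standardized = FALSE) {
  required <- c("study", "agent", "dose", "responders", "sample_size")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  data <- as.data.frame(data)[required]
  data$study <- as.character(data$study)
  data$agent <- as.character(data$agent)
  for (col in c("dose", "responders", "sample_size"))
    data[[col]] <- as.numeric(data[[col]])

  if (anyNA(data))
    stop("missing values in arm data")
  if (any(data$dose < 0))
    stop("negative dose")
  if (any(data$sample_size < 1))
    stop("sample_size must be positive")
  if (any(data$responders < 0) || any(data$responders > data$sample_size))
    stop("responders must lie in [0, sample_size]")
  if (any(data$responders != round(data$responders)) ||
      any(data$sample_size != round(data$sample_size)))
    stop("responders and sample_size must be integer counts")

  common_doses <- normalize_common_doses(common_doses)
  active <- setdiff(unique(data$agent), reference)
  if (!standardized) {
    unmapped <- setdiff(active, names(common_doses))
    if (length(unmapped))
      stop("agent(s) absent from common_doses: ",
           paste(unmapped, collapse = ", "))
    if (any(common_doses[active] <= 0))
      stop("common doses must be positive")
    data$dose_std <- ifelse(data$agent == reference, 0,
                            data$dose / common_doses[data$agent])
  } else {
    data$dose_std <- data$dose
    common_doses <- stats::setNames(rep(1, length(active)), active)
  }
  names(data)[names(data) == "dose"] <- "dose_raw"

  if (any(data$agent == reference & data$dose_std != 0))
    stop("reference agent arms must have dose 0")
  if (any(data$agent != reference & data$dose_std == 0))
    stop("zero dose on a non-reference arm; code it as ", reference)

  studies <- unique(data$study)
  n_arms <- table(data$study)
  singles <- names(n_arms)[n_arms < 2]
  if (length(singles))
    stop("single-arm study: ", paste(singles, collapse = ", "))
  dup <- duplicated(data[c("study", "agent", "dose_std")])
  if (any(dup))
    stop("duplicate (agent, dose) arm within study: ",
         paste(unique(data$study[dup]), collapse = ", "))

  agents <- c(intersect(reference, data$agent),
              setdiff(unique(data$agent), reference))
  net <- structure(
    list(arms = data, studies = studies, agents = agents,
         reference = reference,
         common_doses = common_doses[intersect(names(common_doses), active)],
         coding = "split"),
    class = "dose_network")
  net$arms <- order_reference_arms(net)
  rownames(net$arms) <- NULL
  net
}

normalize_common_doses <- function(common_doses) {
  if (is.null(common_doses)) return(stats::setNames(numeric(0), character(0)))
  if (is.data.frame(common_doses)) {
    if (!all(c("agent", "common_dose") %in% names(common_doses)))
      stop("common-dose table needs columns agent, common_dose")
    return(stats::setNames(as.numeric(common_doses$common_dose),
                           as.character(common_doses$agent)))
  }
  if (is.null(names(common_doses)) && length(common_doses) > 0)
    stop("common_doses must be a named vector or a data.frame")
  common_doses
}

# Move each study's reference arm first: placebo if present, otherwise the
# arm whose split-level treatment has the lowest index.  Remaining arms keep
# input order.
order_reference_arms <- function(net) {
  trt <- treatments(net, level = "treatment")
  arms <- net$arms
  key <- paste(arms$agent, arms$dose_std)
  arms$.t <- match(key, paste(trt$agent, trt$dose_std))
  pieces <- lapply(net$studies, function(s) {
    a <- arms[arms$study == s, , drop = FALSE]
    first <- which.min(a$.t)
    a[c(first, setdiff(seq_len(nrow(a)), first)), , drop = FALSE]
  })
  out <- do.call(rbind, pieces)
  out$.t <- NULL
  out
}

#' Treatment table of a dose network
#'
#' @param net a [dose_network()] object.
#' @param level `"treatment"` for (agent, standardized dose) nodes (split
#'   coding), `"agent"` for agent nodes (lumped coding), or `NULL` to use
#'   the network's current coding.
#' @return data.frame with columns `treatment` (label), `agent`,
#'   `dose_std` (`NA` at agent level), reference node first.
#' @export
treatments <- function(net, level = NULL) {
  stopifnot(inherits(net, "dose_network"))
  level <- level %||% if (net$coding == "lumped") "agent" else "treatment"
  level <- match.arg(level, c("treatment", "agent"))
  if (level == "agent") {
    return(data.frame(treatment = net$agents, agent = net$agents,
                      dose_std = NA_real_, stringsAsFactors = FALSE))
  }
  a <- net$arms
  key <- unique(a[c("agent", "dose_std")])
  key <- key[order(match(key$agent, net$agents), key$dose_std), , drop = FALSE]
  lab <- ifelse(key$agent == net$reference, net$reference,
                sprintf("%s_%g", key$agent, key$dose_std))
  data.frame(treatment = lab, agent = key$agent, dose_std = key$dose_std,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a dose network from a delimited file
#'
#' Reads long-format arm-level data: one row per arm, header columns
#' `study`, `agent`, `dose`, `responders`, `sample_size`.
#'
#' @inheritParams dose_network
#' @param path path to a CSV (or TSV, with `sep = "\t"`) file.
#' @param common_doses as in [dose_network()], or the path of a CSV file
#'   with columns `agent`, `common_dose`.
#' @param sep field separator.
#' @return a [dose_network()] object.
#' @export
read_dose_network <- function(path, common_doses = NULL,
                              reference = "placebo", standardized = FALSE,
                              sep = ",") {
  data <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
  if (is.character(common_doses) && length(common_doses) == 1 &&
      file.exists(common_doses))
    common_doses <- utils::read.table(common_doses, header = TRUE, sep = sep,
                                      stringsAsFactors = FALSE)
  dose_network(data, common_doses = common_doses, reference = reference,
               standardized = standardized)
}

#' Write a dose network back to delimited text
#'
#' Writes the long format read by [read_dose_network()] (raw-unit doses).
#' Reading the file back with the same common-dose table reproduces the
#' network field for field.
#'
#' @param net a [dose_network()] object.
#' @param path output file path.
#' @param sep field separator.
#' @export
write_dose_network <- function(net, path, sep = ",") {
  out <- net$arms[c("study", "agent", "dose_raw", "responders", "sample_size")]
  names(out)[3] <- "dose"
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize the comparison structure of a network
#'
#' One row per unordered pair of nodes that is compared within at least one
#' study, with the number of within-study comparisons (every pair of arms
#' in a study counts one comparison, so a three-arm study contributes one
#' comparison to each of its three edges).  The returned table carries the
#' graph's connectivity as attributes `connected` and `components`.
#'
#' @param net a [dose_network()] object.
#' @param level `"agent"` or `"treatment"`; default follows the network's
#'   coding.
#' @return data.frame with columns `node1`, `node2`, `comparisons`.
#' @export
network_summary <- function(net, level = NULL) {
  stopifnot(inherits(net, "dose_network"))
  level <- level %||% if (net$coding == "lumped") "agent" else "treatment"
  trt <- treatments(net, level = level)
  nodes <- trt$treatment
  idx <- arm_node_index(net, trt, level)
  pair_list <- lapply(net$studies, function(s) {
    v <- sort(unique(idx[net$arms$study == s]))
    if (length(v) < 2) return(NULL)
    t(utils::combn(v, 2))
  })
  pairs <- do.call(rbind, pair_list)
  if (is.null(pairs)) {
    edges <- data.frame(node1 = character(0), node2 = character(0),
                        comparisons = integer(0))
  } else {
    key <- paste(pairs[, 1], pairs[, 2])
    tab <- table(key)
    ij <- do.call(rbind, strsplit(names(tab), " "))
    edges <- data.frame(node1 = nodes[as.integer(ij[, 1])],
                        node2 = nodes[as.integer(ij[, 2])],
                        comparisons = as.integer(tab),
                        stringsAsFactors = FALSE)
    edges <- edges[order(match(edges$node1, nodes),
                         match(edges$node2, nodes)), , drop = FALSE]
    rownames(edges) <- NULL
  }
  comp <- graph_components(length(nodes),
                           cbind(match(edges$node1, nodes),
                                 match(edges$node2, nodes)))
  attr(edges, "connected") <- max(comp) == 1
  attr(edges, "components") <- split(nodes, comp)
  edges
}

arm_node_index <- function(net, trt, level) {
  if (level == "agent") match(net$arms$agent, trt$agent)
  else match(paste(net$arms$agent, net$arms$dose_std),
             paste(trt$agent, trt$dose_std))
}

# Connected components by label propagation; edge matrix may be empty.
graph_components <- function(n_nodes, edges) {
  comp <- seq_len(n_nodes)
  if (n_nodes == 0 || nrow(edges) == 0) return(comp)
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      a <- comp[edges[e, 1]]; b <- comp[edges[e, 2]]
      if (a != b) {
        comp[comp == max(a, b)] <- min(a, b)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, sort(unique(comp)))
}

#' Collapse all doses of each agent to a single node
#'
#' Switches the network to lumped coding, in which every dose of an agent
#' is treated as the same treatment.  Studies containing several arms of
#' one agent are flagged (attribute `multidose_studies`): under lumped
#' coding the mean relative effect between such arms is zero, and in a
#' random-effects model they still inform the between-study heterogeneity.
#'
#' @param net a [dose_network()] object.
#' @return the network with `coding = "lumped"`.
#' @export
lump_doses <- function(net) {
  stopifnot(inherits(net, "dose_network"))
  net$coding <- "lumped"
  dup <- tapply(net$arms$agent, net$arms$study,
                function(a) any(duplicated(a)))
  attr(net, "multidose_studies") <- names(dup)[dup]
  net
}

#' Treat each (agent, dose) combination as its own node
#'
#' Switches the network to split coding.  A split network can be
#' disconnected even when the agent-level network is connected; in that
#' case a warning lists the components, since a disconnected network cannot
#' be fitted jointly.
#'
#' @param net a [dose_network()] object.
#' @return the network with `coding = "split"`.
#' @export
split_doses <- function(net) {
  stopifnot(inherits(net, "dose_network"))
  net$coding <- "split"
  attr(net, "multidose_studies") <- NULL
  es <- network_summary(net, level = "treatment")
  if (!attr(es, "connected")) {
    comps <- attr(es, "components")
    warning("split network is disconnected (",
            length(comps), " components): ",
            paste(vapply(comps, function(x) paste(x, collapse = ","), ""),
                  collapse = " | "))
  }
  net
}

#' @export
print.dose_network <- function(x, ...) {
  es <- network_summary(x)
  cat("Dose network (", x$coding, " coding)\n", sep = "")
  cat("  studies:    ", length(x$studies), "\n", sep = "")
  cat("  arms:       ", nrow(x$arms), "\n", sep = "")
  cat("  agents:     ", length(x$agents), " (reference: ", x$reference,
      ")\n", sep = "")
  cat("  treatments: ", nrow(treatments(x)), "\n", sep = "")
  cat("  edges:      ", nrow(es),
      if (attr(es, "connected")) " (connected)" else " (DISCONNECTED)",
      "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
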