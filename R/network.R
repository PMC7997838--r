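#' Construct a pathway network model
#'
#' An `aromatic_network` couples a set of chemical species to the reactions
#' that interconvert them. Each reaction transforms one substrate into at
#' most one product at 1:1 molar stoichiometry, and carries either a
#' first-order rate law, r = kS, or an inhibition rate law,
#' r = k (k_i / (k_i + S_i)) S, where the inhibitor `S_i` may be another
#' compound (competitive inhibition by a structurally similar substrate) or
#' the substrate itself (substrate self-inhibition at high concentration).
#' Rates are specific rates (umol per mg biomass per h); the network ODE
#' multiplies them by the biomass concentration.
#'
#' Every compound may be consumed by at most one reaction (its single
#' consumption term) but may be produced by several (e.g. an aromatic acid
#' fed by both its amide and its aldehyde). Concentrations are tracked in
#' umol/l throughout; CoA-ligated intermediates accumulate intracellularly
#' and are flagged unmeasurable so they never enter a fit.
#'
#' @param compounds data frame with columns `compound` (unique names),
#'   `class` (one of `"H"`, `"G"`, `"S"`, `"other"`), `measurable` (logical)
#'   and `initial` (umol/l, non-negative).
#' @param reactions data frame with columns `substrate`, `product` (`NA` for
#'   a terminal sink into the benzoyl-CoA pathway), `law` (`"first_order"`
#'   or `"inhibited"`), `k` (l mg^-1 h^-1), `inhibitor` (`NA` unless
#'   inhibited) and `k_i` (umol/l, `NA` unless inhibited).
#' @param free_parameters optional data frame with columns `substrate` and
#'   `param` (`"k"` or `"k_i"`) naming the parameters a fit may vary.
#'   Defaults to every `k` plus every `k_i` of an inhibited reaction.
#' @param check validate the network and abort on violations (default TRUE).
#'
#' @return An object of class `aromatic_network`.
#' @seealso [case_network()], [validate_network()], [simulate_network()]
#' @export
aromatic_network <- function(compounds, reactions, free_parameters = NULL,
                             check = TRUE) {
  compounds <- tibble::as_tibble(compounds)
  reactions <- tibble::as_tibble(reactions)
  need_c <- c("compound", "class", "measurable", "initial")
  need_r <- c("substrate", "product", "law", "k", "inhibitor", "k_i")
  if (!all(need_c %in% names(compounds))) {
    abort(paste0("`compounds` needs columns: ", paste(need_c, collapse = ", ")))
  }
  for (col in setdiff(need_r, names(reactions))) {
    reactions[[col]] <- if (col %in% c("product", "inhibitor")) NA_character_ else NA_real_
  }
  reactions <- reactions[, need_r]
  if (is.null(free_parameters)) {
    free_parameters <- dplyr::bind_rows(
      tibble::tibble(substrate = reactions$substrate, param = "k"),
      tibble::tibble(
        substrate = reactions$substrate[reactions$law == "inhibited"],
        param = "k_i"
      )
    )
  }
  net <- structure(
    list(
      compounds = compounds,
      reactions = reactions,
      free_parameters = tibble::as_tibble(free_parameters)
    ),
    class = "aromatic_network"
  )
  if (check) {
    bad <- validate_network(net)
    if (length(bad) > 0) {
      abort(c("invalid network:", setNames(bad, rep("x", length(bad)))))
    }
  }
  net
}

#' Validate a pathway network
#'
#' Checks the structural invariants of an [aromatic_network()] and returns
#' the violations found rather than raising an error, so candidate networks
#' built by hand or read from a config file can be inspected.
#'
#' Checked: unique compound names; valid class labels; non-negative initial
#' concentrations; substrate/product/inhibitor names resolving within the
#' network; substrate distinct from product; a single consuming reaction per
#' compound; non-negative `k`; positive `k_i` with a named inhibitor for
#' inhibited laws (and neither for first-order laws); an acyclic
#' substrate-to-product graph.
#'
#' @param net an `aromatic_network`.
#' @return A character vector of human-readable violations; empty if valid.
#' @export
validate_network <- function(net) {
  cp <- net$compounds
  rx <- net$reactions
  v <- character()
  if (anyDuplicated(cp$compound)) {
    v <- c(v, paste0("duplicate compound names: ",
                     paste(unique(cp$compound[duplicated(cp$compound)]), collapse = ", ")))
  }
  if (!all(cp$class %in% c("H", "G", "S", "other"))) {
    v <- c(v, "compound class must be one of H, G, S, other")
  }
  if (any(!is.finite(cp$initial) | cp$initial < 0)) {
    v <- c(v, "initial concentrations must be finite and >= 0")
  }
  known <- cp$compound
  for (nm in setdiff(rx$substrate, known)) {
    v <- c(v, paste0("reaction substrate not in compounds: ", nm))
  }
  for (nm in setdiff(rx$product[!is.na(rx$product)], known)) {
    v <- c(v, paste0("reaction product not in compounds: ", nm))
  }
  for (nm in setdiff(rx$inhibitor[!is.na(rx$inhibitor)], known)) {
    v <- c(v, paste0("reaction inhibitor not in compounds: ", nm))
  }
  same <- !is.na(rx$product) & rx$substrate == rx$product
  if (any(same)) {
    v <- c(v, paste0("substrate equals product for: ",
                     paste(rx$substrate[same], collapse = ", ")))
  }
  if (anyDuplicated(rx$substrate)) {
    v <- c(v, paste0("more than one consuming reaction for: ",
                     paste(unique(rx$substrate[duplicated(rx$substrate)]), collapse = ", ")))
  }
  if (any(!is.na(rx$k) & rx$k < 0)) v <- c(v, "rate constants k must be >= 0")
  fo <- rx$law == "first_order"
  if (any(fo & !is.na(rx$inhibitor))) {
    v <- c(v, "first-order reactions must not name an inhibitor")
  }
  inh <- rx$law == "inhibited"
  if (any(inh & is.na(rx$inhibitor))) {
    v <- c(v, "inhibited reactions must name an inhibitor")
  }
  if (any(inh & (is.na(rx$k_i) | rx$k_i <= 0))) {
    v <- c(v, "inhibited reactions must have k_i > 0")
  }
  if (any(!rx$law %in% c("first_order", "inhibited"))) {
    v <- c(v, "rate law must be first_order or inhibited")
  }
  # cycle check on the substrate -> product graph (Kahn's algorithm)
  edges <- rx[!is.na(rx$product) & rx$substrate %in% known & rx$product %in% known,
              c("substrate", "product")]
  if (nrow(edges) > 0) {
    nodes <- unique(c(edges$substrate, edges$product))
    indeg <- setNames(integer(length(nodes)), nodes)
    tab <- table(edges$product)
    indeg[names(tab)] <- as.integer(tab)
    queue <- names(indeg)[indeg == 0]
    removed <- 0L
    while (length(queue) > 0) {
      n <- queue[[1]]; queue <- queue[-1]; removed <- removed + 1L
      for (m in edges$product[edges$substrate == n]) {
        indeg[[m]] <- indeg[[m]] - 1L
        if (indeg[[m]] == 0L) queue <- c(queue, m)
      }
    }
    if (removed < length(nodes)) v <- c(v, "substrate->product graph contains a cycle")
  }
  fp <- net$free_parameters
  if (nrow(fp) > 0) {
    if (!all(fp$param %in% c("k", "k_i"))) v <- c(v, "free parameters must be k or k_i")
    miss <- setdiff(fp$substrate, rx$substrate)
    if (length(miss) > 0) {
      v <- c(v, paste0("free parameter for a substrate with no reaction: ",
                       paste(miss, collapse = ", ")))
    }
    ki_fo <- fp$param == "k_i" &
      fp$substrate %in% rx$substrate[rx$law == "first_order"]
    if (any(ki_fo)) v <- c(v, "k_i cannot be free on a first-order reaction")
  }
  v
}

#' Current values of a network's free parameters
#'
#' Because each compound has at most one consuming reaction, parameters are
#' keyed by the substrate: `"k[ferulic acid]"`, `"k_i[ferulic acid]"`.
#'
#' @param net an `aromatic_network`.
#' @return Named numeric vector, in the network's free-parameter order.
#' @export
network_params <- function(net) {
  fp <- net$free_parameters
  if (nrow(fp) == 0) return(setNames(numeric(), character()))
  rx <- net$reactions
  idx <- match(fp$substrate, rx$substrate)
  val <- ifelse(fp$param == "k", rx$k[idx], rx$k_i[idx])
  setNames(val, paste0(fp$param, "[", fp$substrate, "]"))
}

#' Set free-parameter values on a network
#'
#' @param net an `aromatic_network`.
#' @param params named numeric vector as returned by [network_params()], or
#'   an unnamed vector in the network's free-parameter order.
#' @return The network with the values assigned.
#' @export
set_network_params <- function(net, params) {
  fp <- net$free_parameters
  if (is.null(names(params))) {
    if (length(params) != nrow(fp)) {
      abort("unnamed parameter vector must match the number of free parameters")
    }
    names(params) <- paste0(fp$param, "[", fp$substrate, "]")
  }
  rx <- net$reactions
  for (nm in names(params)) {
    m <- regmatches(nm, regexec("^(k|k_i)\\[(.+)\\]$", nm))[[1]]
    if (length(m) != 3) abort(paste0("malformed parameter name: ", nm))
    i <- match(m[[3]], rx$substrate)
    if (is.na(i)) abort(paste0("no reaction consumes '", m[[3]], "'"))
    if (m[[2]] == "k") rx$k[i] <- params[[nm]] else rx$k_i[i] <- params[[nm]]
  }
  net$reactions <- rx
  net
}

#' @export
print.aromatic_network <- function(x, ...) {
  n_inh <- sum(x$reactions$law == "inhibited")
  cat("<aromatic_network> ", nrow(x$compounds), " compounds (",
      sum(x$compounds$measurable), " measurable), ", nrow(x$reactions),
      " reactions (", n_inh, " inhibited), ", nrow(x$free_parameters),
      " free parameters\n", sep = "")
  print(x$reactions, n = nrow(x$reactions))
  invisible(x)
}
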