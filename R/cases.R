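#' Initial concentrations of aromatic compounds in AFEX corn stover
#' hydrolysate
#'
#' Starting concentrations (umol/l) of the aromatic monomers detected in the
#' ammonia fiber expansion (AFEX) treated corn stover hydrolysate batch
#' medium, used as the default initial conditions of the shipped networks
#' and of the synthetic-data generator. CoA-ligated intermediates are
#' intracellular, start at zero and are not measurable.
#'
#' @return A tibble with columns `compound`, `class`, `measurable`,
#'   `initial`.
#' @export
acsh_initial_concentrations <- function() {
  tibble::tribble(
    ~compound,               ~class,  ~measurable, ~initial,
    "p-coumaroyl amide",      "H",     TRUE,        2090,
    "p-coumaric acid",        "H",     TRUE,        446,
    "p-coumaroyl-CoA",        "H",     FALSE,       0,
    "p-hydroxybenzaldehyde",  "H",     TRUE,        59.4,
    "p-hydroxybenzamide",     "H",     TRUE,        20.6,
    "p-hydroxybenzoic acid",  "H",     TRUE,        47.8,
    "feruloyl amide",         "G",     TRUE,        1040,
    "ferulic acid",           "G",     TRUE,        20.9,
    "feruloyl-CoA",           "G",     FALSE,       0,
    "vanillin",               "G",     TRUE,        43.3,
    "vanillamide",            "G",     TRUE,        60.5,
    "vanillic acid",          "G",     TRUE,        27.0,
    "syringamide",            "S",     TRUE,        32.6,
    "syringaldehyde",         "S",     TRUE,        5.8,
    "syringic acid",          "S",     TRUE,        6.9,
    "benzoic acid",           "other", TRUE,        160,
    "protocatechuic acid",    "other", TRUE,        6.0
  )
}

#' Compounds reported in the H + G comparison, in table order
#' @keywords internal
hg_compound_order <- function() {
  c("p-coumaroyl amide", "p-coumaric acid", "p-hydroxybenzaldehyde",
    "p-hydroxybenzamide", "p-hydroxybenzoic acid",
    "feruloyl amide", "ferulic acid", "vanillin", "vanillamide",
    "vanillic acid")
}

# One row per consuming reaction of the H + G network. The CoA product is
# the aldehyde without channeling and the benzoate directly with channeling.
hg_reactions <- function(channeling) {
  coa_h_product <- if (channeling) "p-hydroxybenzoic acid" else "p-hydroxybenzaldehyde"
  coa_g_product <- if (channeling) "vanillic acid" else "vanillin"
  tibble::tribble(
    ~substrate,               ~product,
    "p-coumaroyl amide",      "p-coumaric acid",
    "p-coumaric acid",        "p-coumaroyl-CoA",
    "p-coumaroyl-CoA",        coa_h_product,
    "p-hydroxybenzaldehyde",  "p-hydroxybenzoic acid",
    "p-hydroxybenzamide",     "p-hydroxybenzoic acid",
    "p-hydroxybenzoic acid",  NA,
    "feruloyl amide",         "ferulic acid",
    "ferulic acid",           "feruloyl-CoA",
    "feruloyl-CoA",           coa_g_product,
    "vanillin",               "vanillic acid",
    "vanillamide",            "vanillic acid",
    "vanillic acid",          NA
  )
}

#' Build one of the five H + G pathway-structure hypotheses
#'
#' The five cases form a ladder of hypotheses about how the p-hydroxyphenyl
#' (H) and guaiacyl (G) aromatic chains are degraded in the hydrolysate
#' mixture:
#'
#' * **Case 1** — no substrate channeling: the CoA-ligated intermediates are
#'   converted to the free aldehydes; every rate law first-order.
#' * **Case 2** — substrate channeling: p-coumaroyl-CoA and feruloyl-CoA are
#'   transformed directly to p-hydroxybenzoic and vanillic acid without
#'   release of the aldehyde; still all first-order. The aldehydes remain in
#'   the network (they are present in the medium) with their own first-order
#'   oxidation to the acids.
#' * **Case 3** — channeling plus competitive inhibition of the G chain by
#'   the structurally analogous H compounds: consumption of feruloyl amide,
#'   ferulic acid and feruloyl-CoA is inhibited by p-coumaroyl amide,
#'   p-coumaric acid and p-coumaroyl-CoA respectively. Vanillic acid keeps a
#'   plain first-order consumption.
#' * **Case 4** — channeling plus substrate self-inhibition of both chains:
#'   p-coumaroyl amide, p-coumaric acid, p-coumaroyl-CoA,
#'   p-hydroxybenzoic acid, feruloyl amide, ferulic acid, feruloyl-CoA and
#'   vanillic acid each inhibit their own consumption.
#' * **Case 5** — hybrid: Case 4's self-inhibition on the four H compounds
#'   plus Case 3's competitive inhibition on the three G steps; vanillic
#'   acid first-order.
#'
#' Cases 2-5 share identical topology and differ only in rate-law kinds and
#' inhibitor assignments. Rate constants ship with nominal
#' placeholder values that act as fit starting points; set them with
#' [set_network_params()] or estimate them with [fit_network()].
#'
#' @param case_id integer 1-5, or a string `"case1"` .. `"case5"`.
#' @param k,k_i default values assigned to every rate constant (l mg^-1
#'   h^-1) / inhibition factor (umol/l); override when constructing a
#'   simulation truth.
#' @return An `aromatic_network` with 12 compounds (10 measurable plus the
#'   two CoA intermediates).
#' @export
case_network <- function(case_id, k = 1e-4, k_i = 100) {
  if (is.character(case_id)) {
    case_id <- match(tolower(case_id), paste0("case", 1:5))
  }
  if (length(case_id) != 1 || is.na(case_id) || !case_id %in% 1:5) {
    abort("`case_id` must be 1..5 or \"case1\"..\"case5\"")
  }
  rx <- hg_reactions(channeling = case_id >= 2)
  rx$law <- "first_order"
  rx$k <- k
  rx$inhibitor <- NA_character_
  rx$k_i <- NA_real_
  h_self <- c("p-coumaroyl amide", "p-coumaric acid", "p-coumaroyl-CoA",
              "p-hydroxybenzoic acid")
  g_competitive <- c(
    "feruloyl amide" = "p-coumaroyl amide",
    "ferulic acid"   = "p-coumaric acid",
    "feruloyl-CoA"   = "p-coumaroyl-CoA"
  )
  set_inhibited <- function(rx, substrates, inhibitors) {
    i <- match(substrates, rx$substrate)
    rx$law[i] <- "inhibited"
    rx$inhibitor[i] <- inhibitors
    rx$k_i[i] <- k_i
    rx
  }
  if (case_id == 3) {
    rx <- set_inhibited(rx, names(g_competitive), unname(g_competitive))
  } else if (case_id == 4) {
    g_self <- c("feruloyl amide", "ferulic acid", "feruloyl-CoA", "vanillic acid")
    rx <- set_inhibited(rx, c(h_self, g_self), c(h_self, g_self))
  } else if (case_id == 5) {
    rx <- set_inhibited(rx, h_self, h_self)
    rx <- set_inhibited(rx, names(g_competitive), unname(g_competitive))
  }
  cp <- dplyr::filter(acsh_initial_concentrations(), .data$class %in% c("H", "G"))
  aromatic_network(cp, rx)
}

#' Build the syringyl (S) aromatic chain
#'
#' Syringyl aromatics with longer alkyl chains were not detected in the
#' hydrolysate, so the S-type model is limited to syringamide and
#' syringaldehyde, both converted to syringic acid, which is slowly consumed
#' to an unmodeled sink. All rate laws are first-order.
#'
#' @inheritParams case_network
#' @return An `aromatic_network` with 3 compounds and 3 reactions.
#' @export
syringyl_network <- function(k = 1e-4) {
  cp <- dplyr::filter(acsh_initial_concentrations(), .data$class == "S")
  rx <- tibble::tribble(
    ~substrate,       ~product,        ~law,          ~k,
    "syringamide",    "syringic acid", "first_order", k,
    "syringaldehyde", "syringic acid", "first_order", k,
    "syringic acid",  NA,              "first_order", k
  )
  aromatic_network(cp, rx)
}

#' Build a single-branch side model
#'
#' Two small first-order models used alongside the H + G comparison:
#' `"benzoic"` is a one-compound first-order decay of benzoic acid into the
#' benzoyl-CoA pathway; `"vanillic_to_pca"` tests whether protocatechuic
#' acid accumulation can be explained as the demethylation product of
#' vanillic acid, with first-order production and consumption.
#'
#' @param which `"benzoic"` or `"vanillic_to_pca"`.
#' @inheritParams case_network
#' @return An `aromatic_network`.
#' @export
side_network <- function(which = c("benzoic", "vanillic_to_pca"), k = 1e-4) {
  which <- match.arg(which)
  all_cp <- acsh_initial_concentrations()
  if (which == "benzoic") {
    cp <- dplyr::filter(all_cp, .data$compound == "benzoic acid")
    rx <- tibble::tibble(substrate = "benzoic acid", product = NA_character_,
                         law = "first_order", k = k)
  } else {
    cp <- dplyr::filter(all_cp, .data$compound %in%
                          c("vanillic acid", "protocatechuic acid"))
    rx <- tibble::tribble(
      ~substrate,            ~product,              ~law,          ~k,
      "vanillic acid",       "protocatechuic acid", "first_order", k,
      "protocatechuic acid", NA,                    "first_order", k
    )
  }
  aromatic_network(cp, rx)
}
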