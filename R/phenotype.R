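#' Additive genotypic values
#'
#' Sums signed additive effects over effect loci for one trait in one
#' environment. At each effect locus the contribution is `+a` for
#' homozygotes of the increasing parent's allele, `-a` for the opposite
#' homozygote and 0 for heterozygotes (purely additive model, no
#' dominance).
#'
#' @param pop A `line_population`.
#' @param effects Effect table with columns `locus_id`, `trait`,
#'   `environment`, `additive_effect`, `increasing_parent`.
#' @param trait Trait label, e.g. `"GY"`.
#' @param environment Environment label (e.g. `"MET"` or `"2006"`), or a
#'   vector of environments whose effects are averaged per locus.
#' @param baseline Zero point added to every value (default 0: values are
#'   relative genotypic values around the midparent).
#' @return Numeric vector, one genotypic value per plant.
#' @export
genotypic_value <- function(pop, effects, trait, environment = "MET",
                            baseline = 0) {
  rows <- effects[effects$trait == trait & effects$environment %in% environment, ,
                  drop = FALSE]
  if (nrow(rows) == 0) return(rep(baseline, n_plants(pop)))
  if (length(environment) > 1) {
    agg <- stats::aggregate(additive_effect ~ locus_id + increasing_parent,
                            data = rows, FUN = mean)
    rows <- agg
  }
  miss <- setdiff(rows$locus_id, pop$map$locus)
  if (length(miss)) stop("effect loci absent from map: ", paste(miss, collapse = ", "))
  j <- match(rows$locus_id, pop$map$locus)
  gcount <- pop$hap1[, j, drop = FALSE] + pop$hap2[, j, drop = FALSE] # C-allele dose
  sign_c <- ifelse(rows$increasing_parent == "C", 1, -1)
  # score s in {-1, 0, +1} relative to the increasing allele
  s <- sweep(gcount - 1L, 2, sign_c, `*`)
  baseline + as.numeric(s %*% rows$additive_effect)
}

#' Predict a trait phenotype for each plant
#'
#' Wraps [genotypic_value()] and reports how many effect loci contributed;
#' an unknown trait/environment combination yields an empty contribution
#' set, which is reported via `n_loci = 0` and a warning rather than being
#' silently treated as zero.
#'
#' @inheritParams genotypic_value
#' @return Data frame with columns `plant`, `trait`, `environment`,
#'   `value`, `baseline` and `n_loci`.
#' @export
predict_phenotype <- function(pop, effects, trait, environment = "MET",
                              baseline = 0) {
  rows <- effects[effects$trait == trait & effects$environment %in% environment, ,
                  drop = FALSE]
  if (nrow(rows) == 0)
    warning("no additive effects found for trait '", trait,
            "' in environment '", paste(environment, collapse = ","),
            "'; returning baseline values")
  v <- genotypic_value(pop, effects, trait, environment, baseline)
  data.frame(plant = seq_len(n_plants(pop)), trait = trait,
             environment = paste(environment, collapse = ","),
             value = v, baseline = baseline,
             n_loci = length(unique(rows$locus_id)))
}

#' Predict a trait across environments
#'
#' Computes per-environment genotypic values for every plant and the
#' across-environment standard deviation per plant. Environments with no
#' effect entries for the trait are reported as missing, not imputed.
#'
#' @inheritParams genotypic_value
#' @param environments Character vector of environment labels.
#' @return List with `values` (matrix plants x available environments),
#'   `sd` (per-plant standard deviation across available environments) and
#'   `missing` (environments with no effects for the trait).
#' @export
predict_over_environments <- function(pop, effects, trait,
                                      environments = c("2005", "2006", "2007", "2008"),
                                      baseline = 0) {
  have <- vapply(environments, function(e)
    any(effects$trait == trait & effects$environment == e), logical(1))
  missing_env <- environments[!have]
  if (length(missing_env))
    warning("no effects for trait '", trait, "' in environment(s): ",
            paste(missing_env, collapse = ", "))
  env <- environments[have]
  vals <- vapply(env, function(e) genotypic_value(pop, effects, trait, e, baseline),
                 numeric(n_plants(pop)))
  if (n_plants(pop) == 1) vals <- matrix(vals, 1, dimnames = list(NULL, env))
  sds <- if (length(env) > 1) apply(vals, 1, stats::sd) else rep(NA_real_, n_plants(pop))
  list(values = vals, sd = sds, missing = missing_env)
}
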