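#' Read a YAML run configuration
#'
#' A run config bundles the specs of a whole experiment under the keys
#' `pretext` (k, overlap, placement, normalize), `encoder`, `train`,
#' `finetune` and `sim`; each present section is converted to the matching
#' spec object, unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return Named list with any of `pretext`, `encoder`, `train`, `finetune`,
#'   `sim`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("pretext", "encoder", "train", "finetune", "sim")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0)
    stop_fc("unknown config section(s): ", paste(extra, collapse = ", "))
  build <- function(section, fun) {
    if (is.null(cfg[[section]])) return(NULL)
    args <- cfg[[section]]
    bad <- setdiff(names(args), names(formals(fun)))
    if (length(bad) > 0)
      stop_fc("unknown key(s) in '", section, "': ",
              paste(bad, collapse = ", "))
    do.call(fun, args)
  }
  out <- list(pretext = build("pretext", pretext_config),
              encoder = build("encoder", encoder_spec),
              train = build("train", train_spec),
              finetune = build("finetune", finetune_spec),
              sim = build("sim", sim_spec))
  out[!vapply(out, is.null, logical(1))]
}
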