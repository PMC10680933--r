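# Classed conditions so callers can distinguish failure modes programmatically.
# Every error inherits from "tsrq_error"; the specific class encodes the stage.

tsrq_abort <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "tsrq_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

size_error        <- function(msg) tsrq_abort(msg, "tsrq_size_error")
parameter_error   <- function(msg) tsrq_abort(msg, "tsrq_parameter_error")
contract_error    <- function(msg) tsrq_abort(msg, "tsrq_contract_error")
no_valid_fov_error<- function(msg) tsrq_abort(msg, "tsrq_no_valid_fov_error")
empty_map_error   <- function(msg) tsrq_abort(msg, "tsrq_empty_map_error")
no_tumor_error    <- function(msg) tsrq_abort(msg, "tsrq_no_tumor_error")
empty_rom_error   <- function(msg) tsrq_abort(msg, "tsrq_empty_rom_error")
empty_tissue_error<- function(msg) tsrq_abort(msg, "tsrq_empty_tissue_error")
consensus_required_error <- function(msg) tsrq_abort(msg, "tsrq_consensus_required_error")
degenerate_input_error   <- function(msg) tsrq_abort(msg, "tsrq_degenerate_input_error")
no_admissible_cutoff_error <- function(msg) tsrq_abort(msg, "tsrq_no_admissible_cutoff_error")
data_error        <- function(msg) tsrq_abort(msg, "tsrq_data_error")
fit_error         <- function(msg) tsrq_abort(msg, "tsrq_fit_error")
spec_error        <- function(msg) tsrq_abort(msg, "tsrq_spec_error")
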