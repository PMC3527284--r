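phase	pattern	cause
pre_execution	missing kind	Job document lacks a task fragment; the submission was malformed.
pre_execution	unknown kind	Job document names a task kind this engine does not provide.
pre_execution	missing model	Job document carries no model; the submission was malformed.
pre_execution	unparseable model	The embedded model document failed to parse; check the model file.
pre_execution	executable not found	The raw-mode executable could not be found on the execute host.
pre_execution	.*	Malformed job specification: the job was held before execution.
post_execution	integration failure	The simulation produced a non-finite state; check rate constants and initial amounts.
post_execution	no steady state	Steady state was not reached within the iteration cap; lengthen the horizon.
post_execution	optimization failure	The objective was non-finite at every probed point; check target and bounds.
post_execution	raw executable exited	The user-supplied executable returned a non-zero exit status.
post_execution	.*	The task was set up incorrectly: the job executed but exited with an error.
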