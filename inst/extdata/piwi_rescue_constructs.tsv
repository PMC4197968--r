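construct_id	length	py	junction_side	junction_distance	expected
int4_isolated	710	poor			DEFECTIVE
int4_pY_fixed	710	good			AUTONOMOUS
int4_60nt	60	poor			AUTONOMOUS
int4_106nt	106	poor			DEFECTIVE
int4_with_int5_200nt_spacer	710	poor	downstream	200	EJC_DEPENDENT
int4_with_int5_500nt_spacer	710	poor	downstream	500	DEFECTIVE
int4_with_int5_900nt_spacer	710	poor	downstream	900	DEFECTIVE
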