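patient	overlap	preop_vf	postop_vf
Patient04	yes	normal	abnormal
Patient09	no	normal	normal
Patient13	yes	normal	abnormal
Patient15	yes	normal	abnormal
Patient17	no	normal	normal
Patient18	yes	normal	abnormal
Patient25	no	normal	normal
Patient31	no	normal	normal
Patient32	no	normal	normal
Patient39	yes	normal	abnormal
Patient42	yes	normal	abnormal
Patient43	yes	normal	abnormal
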