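animal	late_puberty	testis	prostate	kidney	obesity	tumor
PS1	-	-	-	-	-	-
PS2	-	-	-	-	-	-
PS3	-	+	-	-	-	-
PS4	-	+	-	-	-	-
PS5	-	-	-	-	-	-
PS6	-	-	-	-	-	-
PS7	-	-	-	-	-	-
PS8	-	-	-	-	-	-
PS9	-	+	-	-	-	-
PS10	-	-	-	-	-	-
PS11	-	-	-	-	-	-
PS12	-	-	-	-	-	-
PS13	-	-	-	-	-	-
PS14	-	+	-	+	-	-
PS15	-	-	-	-	-	-
PS16	-	-	-	+	-	-
PS17	-	n/a	+	-	-	-
PS18	-	-	-	-	-	-
PS19	-	-	+	-	-	-
PS20	-	+	+	+	+	-
PS21	-	-	-	-	-	-
PS22	-	+	+	-	-	-
PS23	-	-	-	+	-	-
PS24	-	-	-	-	-	-
PS25	-	-	-	+	-	-
PS26	-	-	+	-	-	-
PS27	+	+	-	+	+	-
PS28	-	-	-	+	-	-
PS29	-	+	-	-	+	-
PS30	-	+	-	+	-	-
PS31	-	-	-	+	-	-
PS32	+	+	-	-	-	-
PS33	+	-	-	-	-	-
PS34	+	-	-	+	-	-
PS35	n/a	+	+	-	-	-
PS36	n/a	+	-	+	-	-
PS37	n/a	+	+	+	-	-
PS38	n/a	+	-	+	-	-
PS39	-	-	-	-	-	+
PS40	-	-	+	-	-	-
PS41	-	-	-	+	-	-
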